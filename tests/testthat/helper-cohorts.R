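# Small cohort builders shared across test files.  Everything is generated
# in code at test time; seeds are fixed so expectations are stable.

tiny_config <- function(n_per_group = 2, n_trials = 40, seed = 11, ...) {
  ground_truth_config(n_per_group = n_per_group, n_trials = n_trials,
                      seed = seed, ...)
}

# A deterministic hand-built subject-parameter table (bypasses the random
# group-level draw when tests need exact generating values).
manual_subject_params <- function(ids, w_taste = 0.6, w_health = 0.1,
                                  bias = 0.5, boundary = 1.4, ndt = 0.3,
                                  drift_noise_var = 0) {
  data.frame(participant_id = ids, group = "control",
             w_taste = w_taste, w_health = w_health, bias = bias,
             boundary = boundary, ndt = ndt,
             drift_noise_var = drift_noise_var,
             stringsAsFactors = FALSE)
}

# Rating/trial scaffold without choices, for simulate_choice_rt tests.
manual_trials <- function(ids, n_trials, seed = 5) {
  set.seed(seed)
  n <- length(ids) * n_trials
  data.frame(
    participant_id = rep(ids, each = n_trials),
    trial_index = rep(seq_len(n_trials), length(ids)),
    taste = sample(c(-2, -1, 1, 2), n, replace = TRUE),
    health = sample(c(-2, -1, 1, 2), n, replace = TRUE),
    sv = sample(c(-2, -1, 1, 2), n, replace = TRUE),
    calorie_density = stats::rlnorm(n, log(1.5), 0.5),
    stringsAsFactors = FALSE
  )
}

# One small fitted model reused by several test files (built lazily once).
.shared <- new.env(parent = emptyenv())

shared_small_fit <- function() {
  if (!is.null(.shared$fit)) return(.shared)
  cfg <- tiny_config(n_per_group = 1, n_trials = 60, seed = 21)
  study <- generate_study(cfg)
  model <- build_ddm_model(study$trials, "two_weight")
  .shared$study <- study
  .shared$model <- model
  .shared$fit <- sample_posterior(model, n_chains = 2, n_iter = 300,
                                  burn_in = 300, thin = 3,
                                  seeds = c(61, 62))
  .shared
}
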