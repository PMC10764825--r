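#' Ground-truth configuration for synthetic study cohorts
#'
#' Bundles every generating parameter of the synthetic placebo-suggestion
#' study: per-group means and SDs of the subject-level diffusion parameters,
#' rating and calorie-density distributions, hunger/expectancy effects and
#' the mediation path coefficients.  The default group means encode the
#' reported posterior group differences: taste weight (increased -
#' decreased) = 0.20, health weight (decreased - increased) = 0.06 and
#' starting bias (increased - decreased) = 0.04, with the control group
#' placed to match its printed contrasts as well.
#'
#' @param n_per_group participants per group (single integer or named
#'   vector over `decreased`, `control`, `increased`).
#' @param n_trials dietary-choice trials per participant.
#' @param groups named list of per-group parameter means/SDs; see defaults.
#' @param rating_probs probabilities of the rating codes -2, -1, 1, 2
#'   (named vector summing to 1) used independently for taste and health.
#' @param rating_correlation Gaussian-copula correlation between taste and
#'   health ratings (default 0: independent).
#' @param calorie_meanlog,calorie_sdlog log-normal calorie-density
#'   parameters (kcal per 100 g/ml); default median 1.48.
#' @param hunger,expectancy lists of generating parameters for the 7-point
#'   composite hunger and 10-point expectancy ratings.
#' @param mediation list with `a_true`, `b_true`, `c_direct_true`, `sd_m`,
#'   `sd_y` for the group -> ROI -> hunger-change chain.
#' @param sv list of weights generating the 4-point stimulus-value rating
#'   from taste/health ratings.
#' @param dt,max_time Euler step and censoring horizon (seconds) for the
#'   choice/RT simulator.
#' @param seed integer seed; recorded in all outputs.
#' @return A list of class `ground_truth_config`.
#' @export
ground_truth_config <- function(
    n_per_group = 28,
    n_trials = 152,
    groups = list(
      decreased = list(w_taste = 0.50, w_health = 0.10, bias = 0.52,
                       boundary = 1.40, ndt = 0.35, drift_noise_var = 0.30),
      control   = list(w_taste = 0.66, w_health = 0.14, bias = 0.57,
                       boundary = 1.40, ndt = 0.35, drift_noise_var = 0.30),
      increased = list(w_taste = 0.70, w_health = 0.04, bias = 0.56,
                       boundary = 1.40, ndt = 0.35, drift_noise_var = 0.30)
    ),
    subject_sd = list(w_taste = 0.15, w_health = 0.08, bias = 0.04,
                      boundary = 0.15, ndt = 0.08, drift_noise_var = 0.08),
    rating_probs = c(`-2` = 0.25, `-1` = 0.25, `1` = 0.25, `2` = 0.25),
    rating_correlation = 0,
    calorie_meanlog = log(1.48), calorie_sdlog = 0.7,
    hunger = list(baseline_mean = 4.2, baseline_sd = 1.2,
                  delta_mean = c(decreased = 0.21, control = 0.60,
                                 increased = 0.96),
                  delta_sd = 1.1),
    expectancy = list(mean = c(decreased = 5.6, control = 4.3,
                               increased = 5.3),
                      sd = 1.9),
    mediation = list(a_true = 0.5, b_true = 0.4, c_direct_true = 0.21,
                     sd_m = 1.0, sd_y = 1.0),
    sv = list(w_taste = 0.55, w_health = 0.12, noise_sd = 0.5),
    dt = 0.008, max_time = 10,
    seed = 1L) {
  group_names <- c("decreased", "control", "increased")
  stopifnot(setequal(names(groups), group_names))
  if (length(n_per_group) == 1L)
    n_per_group <- stats::setNames(rep(as.integer(n_per_group), 3L),
                                   group_names)
  stopifnot(setequal(names(n_per_group), group_names),
            all(n_per_group >= 1L))
  check_rating_distribution(rating_probs)
  stopifnot(abs(rating_correlation) < 1)
  sds <- unlist(subject_sd)
  if (any(sds <= 0)) stop("all subject-level SDs must be strictly positive")
  if (is.null(seed) || !is.finite(seed))
    stop("a seed is required for deterministic generation")
  structure(list(
    n_per_group = n_per_group[group_names], n_trials = as.integer(n_trials),
    groups = groups[group_names], subject_sd = subject_sd,
    rating_probs = rating_probs, rating_correlation = rating_correlation,
    calorie_meanlog = calorie_meanlog, calorie_sdlog = calorie_sdlog,
    hunger = hunger, expectancy = expectancy, mediation = mediation,
    sv = sv, dt = dt, max_time = max_time, seed = as.integer(seed)
  ), class = "ground_truth_config")
}

check_rating_distribution <- function(probs) {
  codes <- c("-2", "-1", "1", "2")
  if (!setequal(names(probs), codes))
    stop("rating distribution must be named over the codes -2, -1, 1, 2 ",
         "(0 is not a legal rating)", call. = FALSE)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("rating probabilities must be non-negative and sum to 1",
         call. = FALSE)
  invisible(probs)
}

# Truncated-normal draws by inverse CDF; sd = 0 degenerates to the mean.
rtnorm <- function(n, mean, sd, lo, hi) {
  if (length(sd) == 1L && sd == 0) return(pmin(pmax(rep(mean, n), lo), hi))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  q <- stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
  pmin(pmax(q, lo), hi)
}

#' Generate the synthetic participant table
#'
#' Builds a balanced three-group cohort by a seeded permutation of the group
#' labels, with BMI, baseline/end composite hunger (7-point scale) and
#' expectancy (10-point scale) drawn from the configured truncated normals.
#'
#' @param config a [ground_truth_config()].
#' @return data.frame with one row per participant: `participant_id`,
#'   `group`, `bmi`, `baseline_hunger`, `end_hunger`, `expectancy`.
#' @export
generate_participants <- function(config) {
  stopifnot(inherits(config, "ground_truth_config"))
  set.seed(config$seed)
  labels <- rep(names(config$n_per_group), times = config$n_per_group)
  group <- sample(labels)                       # seeded permutation
  n <- length(group)
  baseline <- rtnorm(n, config$hunger$baseline_mean,
                     config$hunger$baseline_sd, 1, 7)
  delta <- rtnorm(n, config$hunger$delta_mean[group],
                  config$hunger$delta_sd, -6, 6)
  data.frame(
    participant_id = seq_len(n),
    group = factor(group, levels = names(config$n_per_group)),
    bmi = rtnorm(n, 23, 3, 16, 40),
    baseline_hunger = baseline,
    end_hunger = pmin(pmax(baseline + delta, 1), 7),
    expectancy = rtnorm(n, config$expectancy$mean[group],
                        config$expectancy$sd, 1, 10),
    stringsAsFactors = FALSE
  )
}

# Draw categorical ratings from the 4-point code via a Gaussian copula so a
# taste/health correlation can be induced; r = 0 gives independent draws.
draw_rating_pair <- function(n, probs, r) {
  cum <- cumsum(probs)
  codes <- as.numeric(names(probs))
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  cut_codes <- function(z) codes[findInterval(stats::pnorm(z),
                                              cum[-length(cum)]) + 1L]
  list(taste = cut_codes(z1), health = cut_codes(z2))
}

#' Generate dietary-choice trials (ratings and calorie densities)
#'
#' Each participant receives `n_trials` rows with taste and health ratings
#' drawn from the configured 4-point distribution (optionally correlated), a
#' 4-point stimulus-value rating generated by linear attribute integration
#' plus noise, and a positive log-normal calorie density.  Choices and
#' response times are added separately by [simulate_choice_rt()].
#'
#' @param participants output of [generate_participants()].
#' @param config a [ground_truth_config()].
#' @return data.frame of trial rows without `choice`/`rt_signed`.
#' @export
generate_trials <- function(participants, config) {
  stopifnot(inherits(config, "ground_truth_config"))
  check_rating_distribution(config$rating_probs)
  set.seed(config$seed + 1L)
  n <- nrow(participants) * config$n_trials
  ratings <- draw_rating_pair(n, config$rating_probs,
                              config$rating_correlation)
  sv_latent <- config$sv$w_taste * ratings$taste +
    config$sv$w_health * ratings$health +
    stats::rnorm(n, 0, config$sv$noise_sd)
  sv <- c(-2, -1, 1, 2)[findInterval(sv_latent, c(-1, 0, 1)) + 1L]
  data.frame(
    participant_id = rep(participants$participant_id,
                         each = config$n_trials),
    trial_index = rep(seq_len(config$n_trials), nrow(participants)),
    taste = ratings$taste,
    health = ratings$health,
    sv = sv,
    calorie_density = stats::rlnorm(n, config$calorie_meanlog,
                                    config$calorie_sdlog),
    stringsAsFactors = FALSE
  )
}

#' Draw subject-level diffusion parameters from the group-level truth
#'
#' @param participants output of [generate_participants()].
#' @param config a [ground_truth_config()].
#' @return data.frame with one row per participant: `participant_id`,
#'   `group`, `w_taste`, `w_health`, `bias`, `boundary`, `ndt`,
#'   `drift_noise_var`.
#' @export
draw_subject_params <- function(participants, config) {
  stopifnot(inherits(config, "ground_truth_config"))
  set.seed(config$seed + 2L)
  g <- as.character(participants$group)
  gm <- function(field) vapply(g, function(x) config$groups[[x]][[field]],
                               numeric(1))
  sd_of <- function(field) config$subject_sd[[field]]
  n <- nrow(participants)
  data.frame(
    participant_id = participants$participant_id,
    group = participants$group,
    w_taste = rtnorm(n, gm("w_taste"), sd_of("w_taste"), -5, 5),
    w_health = rtnorm(n, gm("w_health"), sd_of("w_health"), -5, 5),
    bias = rtnorm(n, gm("bias"), sd_of("bias"), 0.01, 0.99),
    boundary = rtnorm(n, gm("boundary"), sd_of("boundary"), 0.2, 2),
    ndt = rtnorm(n, gm("ndt"), sd_of("ndt"), 0.05, 2),
    drift_noise_var = rtnorm(n, gm("drift_noise_var"),
                             sd_of("drift_noise_var"), 0.001, 2),
    stringsAsFactors = FALSE
  )
}

#' Simulate choices and response times for a trial table
#'
#' For every trial the drift rate is drawn from
#' `N(w_taste * taste + w_health * health, drift_noise_var)` and the
#' diffusion path is simulated by Euler-Maruyama.  "Yes" choices get
#' positive and "no" choices negative signed response times.  Trials that
#' do not reach a boundary within the censoring horizon are dropped, with
#' the count recorded in the `censored_trials` attribute and a message.
#'
#' @param trials output of [generate_trials()].
#' @param subject_params output of [draw_subject_params()].
#' @param dt Euler step in seconds.
#' @param seed integer seed.
#' @param max_time censoring horizon for the decision time, seconds.
#' @return The completed trial table (columns of `trials` plus `choice`,
#'   `rt_signed`), censored trials excluded.
#' @export
simulate_choice_rt <- function(trials, subject_params, dt = 0.008,
                               seed = 1L, max_time = 10) {
  stopifnot(dt > 0, all(trials$participant_id %in%
                          subject_params$participant_id))
  set.seed(seed)
  out <- vector("list", nrow(subject_params))
  for (i in seq_len(nrow(subject_params))) {
    sp <- subject_params[i, ]
    tr <- trials[trials$participant_id == sp$participant_id, , drop = FALSE]
    if (nrow(tr) == 0L) next
    m <- drift_mean(sp$w_taste, sp$w_health, tr$taste, tr$health)
    delta <- stats::rnorm(nrow(tr), m, sqrt(sp$drift_noise_var))
    sim <- simulate_wiener_cpp(delta, sp$boundary, sp$bias, sp$ndt, dt,
                               max_time)
    tr$choice <- ifelse(is.na(sim[, 1]), NA_character_,
                        ifelse(sim[, 1] > 0, "yes", "no"))
    tr$rt_signed <- sim[, 1]
    out[[i]] <- tr
  }
  completed <- do.call(rbind, out)
  n_censored <- sum(is.na(completed$rt_signed))
  if (n_censored > 0)
    message(sprintf("excluding %d censored trial(s) (no boundary hit within %g s)",
                    n_censored, max_time))
  completed <- completed[!is.na(completed$rt_signed), , drop = FALSE]
  rownames(completed) <- NULL
  attr(completed, "censored_trials") <- n_censored
  completed
}

#' Generate the per-participant mediation table
#'
#' Builds the group -> ROI activation -> hunger-change chain for the two
#' suggestion groups only: `X` is -1 (decreased) or +1 (increased),
#' `M = a_true * X + noise`, `Y = b_true * M + c_direct_true * X + noise`.
#' The true indirect effect `a_true * b_true` is recorded in the
#' `truth` attribute.
#'
#' @param participants participant table containing only decreased and
#'   increased suggestion rows; control rows are rejected.
#' @param config a [ground_truth_config()].
#' @param roi label carried through to the output (default "dlPFC").
#' @return data.frame with `participant_id`, `roi`, `X`, `M`, `Y`.
#' @export
generate_mediation_table <- function(participants, config, roi = "dlPFC") {
  stopifnot(inherits(config, "ground_truth_config"))
  if (any(participants$group == "control"))
    stop("mediation operates on the decreased/increased suggestion groups ",
         "only; remove control-group rows first", call. = FALSE)
  set.seed(config$seed + 3L)
  med <- config$mediation
  x <- ifelse(participants$group == "increased", 1, -1)
  m <- med$a_true * x + stats::rnorm(length(x), 0, med$sd_m)
  y <- med$b_true * m + med$c_direct_true * x +
    stats::rnorm(length(x), 0, med$sd_y)
  out <- data.frame(participant_id = participants$participant_id,
                    roi = roi, X = x, M = m, Y = y,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(a_true = med$a_true, b_true = med$b_true,
                             c_direct_true = med$c_direct_true,
                             indirect_true = med$a_true * med$b_true)
  out
}

#' Generate a complete synthetic study dataset
#'
#' Convenience wrapper running the whole generator: participants, subject
#' diffusion parameters, trial ratings, simulated choices/RTs and the
#' mediation table, all deterministic functions of the configuration seed.
#'
#' @param config a [ground_truth_config()].
#' @return list of class `synthetic_study` with elements `participants`,
#'   `subject_params`, `trials`, `mediation` and `config`.
#' @export
generate_study <- function(config = ground_truth_config()) {
  participants <- generate_participants(config)
  subject_params <- draw_subject_params(participants, config)
  trials <- generate_trials(participants, config)
  trials <- simulate_choice_rt(trials, subject_params, dt = config$dt,
                               seed = config$seed + 4L,
                               max_time = config$max_time)
  suggestion <- participants[participants$group != "control", , drop = FALSE]
  mediation <- generate_mediation_table(suggestion, config)
  structure(list(participants = participants,
                 subject_params = subject_params,
                 trials = trials, mediation = mediation, config = config),
            class = "synthetic_study")
}

#' Write a synthetic dataset to CSV files plus a truth sidecar
#'
#' Writes `participants.csv`, `trials.csv` and `mediation.csv` (atomic
#' writes) and a `truth.json` sidecar recording every generating parameter
#' and the seed.
#'
#' @param study output of [generate_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    participants = write_csv_atomic(study$participants,
                                    file.path(dir, "participants.csv")),
    trials = write_csv_atomic(study$trials, file.path(dir, "trials.csv")),
    mediation = write_csv_atomic(study$mediation,
                                 file.path(dir, "mediation.csv"))
  )
  truth <- study$config
  truth$subject_params <- study$subject_params
  truth$mediation_truth <- attr(study$mediation, "truth")
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(c(paths, truth = truth_path))
}
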