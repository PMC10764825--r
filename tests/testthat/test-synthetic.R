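test_that("participant generation is balanced, bounded and deterministic", {
  cfg <- tiny_config(n_per_group = 3, seed = 4)
  pp <- generate_participants(cfg)
  expect_equal(nrow(pp), 9)
  expect_equal(unname(table(pp$group)[c("decreased", "control", "increased")]),
               rep(3L, 3), ignore_attr = TRUE)
  expect_true(all(pp$baseline_hunger >= 1 & pp$baseline_hunger <= 7))
  expect_true(all(pp$end_hunger >= 1 & pp$end_hunger <= 7))
  expect_true(all(pp$expectancy >= 1 & pp$expectancy <= 10))
  # same config, same seed: byte-identical tables
  expect_identical(pp, generate_participants(cfg))
  # degenerate SD collapses expectancy onto its mean
  cfg0 <- tiny_config(seed = 4, expectancy = list(
    mean = c(decreased = 5.5, control = 5.5, increased = 5.5), sd = 0))
  expect_true(all(generate_participants(cfg0)$expectancy == 5.5))
  expect_error(ground_truth_config(n_per_group = 0), "n_per_group")
  expect_error(ground_truth_config(seed = NULL), "seed")
})

test_that("trial ratings follow the configured 4-point distribution", {
  cfg <- tiny_config(n_per_group = 1, n_trials = 4000, seed = 8)
  pp <- generate_participants(cfg)
  tr <- generate_trials(pp, cfg)
  expect_equal(nrow(tr), 3 * 4000)
  expect_true(all(tr$taste %in% c(-2, -1, 1, 2)))
  expect_true(all(tr$sv %in% c(-2, -1, 1, 2)))
  expect_true(all(tr$calorie_density > 0))
  freq <- table(factor(tr$taste, levels = c(-2, -1, 1, 2))) / nrow(tr)
  expect_true(all(abs(freq - 0.25) < 0.02))
  # point mass puts every rating on one code
  cfg2 <- tiny_config(n_trials = 30, seed = 8, rating_probs =
                        c(`-2` = 0, `-1` = 0, `1` = 0, `2` = 1))
  tr2 <- generate_trials(generate_participants(cfg2), cfg2)
  expect_true(all(tr2$taste == 2))
  # zero is never a legal rating code
  expect_error(ground_truth_config(rating_probs =
    c(`0` = 0.25, `-1` = 0.25, `1` = 0.25, `2` = 0.25)), "0 is not")
  expect_error(ground_truth_config(rating_probs =
    c(`-2` = 0.5, `-1` = 0.25, `1` = 0.25, `2` = 0.25)), "sum to 1")
})

test_that("trial count per participant matches the task design", {
  cfg <- tiny_config(n_per_group = 1, n_trials = 152, seed = 2)
  tr <- generate_trials(generate_participants(cfg), cfg)
  expect_equal(unname(table(tr$participant_id)), rep(152L, 3),
               ignore_attr = TRUE)
})

test_that("rating correlation knob induces the requested association", {
  cfg <- tiny_config(n_per_group = 1, n_trials = 5000, seed = 13,
                     rating_correlation = 0.8)
  tr <- generate_trials(generate_participants(cfg), cfg)
  expect_gt(cor(tr$taste, tr$health), 0.5)
})

test_that("simulated choices and RTs respect the diffusion structure", {
  sp <- manual_subject_params(1:2, w_taste = 0, w_health = 0, bias = 0.5,
                              boundary = 1.5, ndt = 0.3)
  tr <- manual_trials(1:2, 2000)
  done <- simulate_choice_rt(tr, sp, seed = 7)
  # sign of rt encodes the choice; |rt| always exceeds the non-decision time
  expect_true(all((done$choice == "yes") == (done$rt_signed > 0)))
  expect_true(all(abs(done$rt_signed) > 0.3))
  # drift-free symmetric process: P(yes) near one half
  expect_lt(abs(mean(done$choice == "yes") - 0.5), 0.025)
  # positive taste weight: tasty food chosen more often
  sp2 <- manual_subject_params(1, w_taste = 0.8, w_health = 0)
  done2 <- simulate_choice_rt(manual_trials(1, 3000, seed = 6), sp2,
                              seed = 8)
  p_yes <- tapply(done2$choice == "yes", done2$taste, mean)
  expect_gt(p_yes[["2"]], p_yes[["-2"]])
})

test_that("mediation table encodes the configured causal chain", {
  cfg <- tiny_config(n_per_group = 4, seed = 31)
  pp <- generate_participants(cfg)
  sugg <- pp[pp$group != "control", ]
  expect_error(generate_mediation_table(pp, cfg), "control")
  med <- generate_mediation_table(sugg, cfg)
  expect_true(all(med$X %in% c(-1, 1)))
  expect_equal(attr(med, "truth")$indirect_true,
               cfg$mediation$a_true * cfg$mediation$b_true)
  # noiseless unit chain with no direct effect: Y = X exactly
  cfg0 <- tiny_config(n_per_group = 4, seed = 31, mediation = list(
    a_true = 1, b_true = 1, c_direct_true = 0, sd_m = 0, sd_y = 0))
  med0 <- generate_mediation_table(sugg, cfg0)
  expect_equal(med0$Y, med0$X, tolerance = 1e-12)
  expect_equal(med0$M, med0$X, tolerance = 1e-12)
})

test_that("mediation generator is recovered by the path regressions", {
  cfg <- ground_truth_config(n_per_group = 100, seed = 17)
  pp <- generate_participants(cfg)
  sugg <- pp[pp$group != "control", ]          # about 200 records
  med <- generate_mediation_table(sugg, cfg)
  fit <- fit_mediation_paths(med)
  # OLS SEs from the two regressions (independent oracle via lm)
  se_a <- summary(lm(M ~ X, med))$coefficients["X", "Std. Error"]
  se_b <- summary(lm(Y ~ M + X, med))$coefficients["M", "Std. Error"]
  expect_lt(abs(fit$a - cfg$mediation$a_true), 2 * se_a)
  expect_lt(abs(fit$b - cfg$mediation$b_true), 2 * se_b)
  # null a path: estimate near zero at large n
  cfg0 <- ground_truth_config(n_per_group = 400, seed = 18, mediation =
    list(a_true = 0, b_true = 0.4, c_direct_true = 0.2, sd_m = 1, sd_y = 1))
  pp0 <- generate_participants(cfg0)
  med0 <- generate_mediation_table(pp0[pp0$group != "control", ], cfg0)
  expect_lt(abs(fit_mediation_paths(med0)$a), 0.15)
})

test_that("default ground truth encodes the reported group differences", {
  cfg <- ground_truth_config()
  g <- cfg$groups
  expect_equal(g$increased$w_taste - g$decreased$w_taste, 0.20)
  expect_equal(g$decreased$w_health - g$increased$w_health, 0.06)
  expect_equal(g$increased$bias - g$decreased$bias, 0.04)
  # and the subject draw reproduces the taste gap in expectation: the
  # mean over replicate n = 30/group draws concentrates on 0.20
  gaps <- vapply(1:8, function(s) {
    cfg30 <- ground_truth_config(n_per_group = 30, seed = s)
    sp <- draw_subject_params(generate_participants(cfg30), cfg30)
    mean(sp$w_taste[sp$group == "increased"]) -
      mean(sp$w_taste[sp$group == "decreased"])
  }, numeric(1))
  expect_lt(abs(mean(gaps) - 0.20), 0.05)
  # a single n = 30/group draw sits within Monte-Carlo range of 0.20
  expect_lt(abs(gaps[1] - 0.20), 3 * 0.15 * sqrt(2 / 30))
})

test_that("whole-study generation is a pure function of the config", {
  cfg <- tiny_config(seed = 99)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$participants, s2$participants)
  expect_identical(s1$mediation, s2$mediation)
})

test_that("synthetic datasets round-trip through the CSV writer", {
  cfg <- tiny_config(seed = 3)
  study <- generate_study(cfg)
  dir <- tempfile("synth_")
  paths <- write_synthetic_dataset(study, dir)
  expect_true(all(file.exists(paths)))
  back <- read_trial_table(file.path(dir, "trials.csv"))
  expect_equal(back$rt_signed, study$trials$rt_signed, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, cfg$seed)
  unlink(dir, recursive = TRUE)
})
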