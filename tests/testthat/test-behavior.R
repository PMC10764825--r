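make_valuation_trials <- function(n = 60, seed = 1) {
  set.seed(seed)
  data.frame(
    participant_id = 1,
    trial_index = seq_len(n),
    taste = sample(c(-2, -1, 1, 2), n, replace = TRUE),
    health = sample(c(-2, -1, 1, 2), n, replace = TRUE),
    sv = 0, stringsAsFactors = FALSE
  )
}

test_that("valuation regression recovers noiseless generating weights", {
  tr <- make_valuation_trials()
  tr$sv <- 0.5 * (tr$taste - mean(tr$taste))
  b <- valuation_glm(tr)
  expect_equal(b$beta_TR, 0.5, tolerance = 1e-10)
  for (cc in c("beta_HR", "beta_trial", "beta_HRxTR", "beta_HRxtrial",
               "beta_TRxtrial"))
    expect_equal(b[[cc]], 0, tolerance = 1e-10)
  expect_error(valuation_glm(tr[1:5, ]), "at least 10")
})

test_that("valuation estimates equal the normal-equations solution", {
  tr <- make_valuation_trials(n = 80, seed = 7)
  set.seed(8)
  tr$sv <- 0.3 * tr$taste + 0.1 * tr$health - 0.002 * tr$trial_index +
    rnorm(80, 0, 0.4)
  b <- valuation_glm(tr)
  HR <- tr$health - mean(tr$health)
  TR <- tr$taste - mean(tr$taste)
  trl <- tr$trial_index - mean(tr$trial_index)
  X <- cbind(1, HR, TR, trl, HR * TR, HR * trl, TR * trl)
  beta <- solve(t(X) %*% X, t(X) %*% tr$sv)
  expect_equal(unlist(b[c("beta0", "beta_HR", "beta_TR", "beta_trial",
                          "beta_HRxTR", "beta_HRxtrial", "beta_TRxtrial")]),
               drop(beta), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("second-level t-tests behave at fixtures and null groups", {
  set.seed(3)
  betas <- function(mu, n) {
    d <- as.data.frame(matrix(rnorm(7 * n, mu, 0.1), ncol = 7))
    names(d) <- c("beta0", "beta_HR", "beta_TR", "beta_trial", "beta_HRxTR",
                  "beta_HRxtrial", "beta_TRxtrial")
    d
  }
  # identical groups: two-sample t exactly 0, p exactly 1
  g <- betas(0.5, 10)
  tab <- second_level_ttests(list(a = g, b = g))
  two <- tab[tab$test == "two_sample", ]
  expect_true(all(two$t == 0) && all(two$p == 1))
  # strong effect at n = 30: one-sample t significant well below 0.001
  tab2 <- second_level_ttests(list(a = betas(0.5, 30)))
  expect_true(all(tab2$p < 1e-3))
  # hand formula on a 4-subject fixture
  x <- c(0.1, 0.3, 0.2, 0.4)
  y <- c(0.0, 0.1, -0.1, 0.05)
  fx <- betas(0, 4); fx$beta_TR <- x
  fy <- betas(0, 4); fy$beta_TR <- y
  tab3 <- second_level_ttests(list(gx = fx, gy = fy))
  sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
  t_hand <- (mean(x) - mean(y)) / (sp * sqrt(1 / 4 + 1 / 4))
  got <- tab3[tab3$test == "two_sample" & tab3$coefficient == "beta_TR", ]
  expect_equal(got$t, t_hand, tolerance = 1e-10)
  expect_error(second_level_ttests(list(a = betas(0, 1))), "at least 2")
})

test_that("calorie median split sends ties to the low half", {
  expect_equal(as.character(calorie_median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(calorie_median_split(c(1, 2, 3))),
               c("low", "low", "high"))
  # label multiset is order invariant
  x <- c(5, 1, 3, 2, 8, 2)
  expect_equal(table(calorie_median_split(x)),
               table(calorie_median_split(rev(x))))
  expect_error(calorie_median_split(rep(2, 5)), "distinct")
})

test_that("Fisher r-to-z contrast matches its sampling theory", {
  eq <- fisher_r_to_z(0.3, 100, 0.3, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  expect_equal(fisher_r_to_z(0.4, 50, 0.1, 80)$z,
               -fisher_r_to_z(0.1, 80, 0.4, 50)$z)
  # the calorie-correlation contrast at the reported inputs
  res <- fisher_r_to_z(0.17, 255, -0.12, 255)
  expect_equal(res$z, 3.28, tolerance = 0.005)
  expect_lt(res$p, 0.0015)
  expect_error(fisher_r_to_z(1, 10, 0, 10))
})

test_that("composite hunger is the mean of three in-scale ratings", {
  expect_equal(composite_hunger(c(3, 4, 5)), 4)
  expect_equal(composite_hunger(c(7, 7, 7)), 7)
  expect_equal(composite_hunger(c(5, 3, 4)), composite_hunger(c(3, 4, 5)))
  expect_error(composite_hunger(c(3, 4)), "three")
  expect_error(composite_hunger(c(0, 4, 5)), "7-point")
})

test_that("sample-size search returns the minimal noncentral-t n", {
  r80 <- sample_size_ttest(0.5, power = 0.80, alpha = 0.05, tails = 1)
  expect_equal(r80$n_per_group, 51)
  expect_equal(r80$n_total, 102)
  r85 <- sample_size_ttest(0.5, power = 0.85, alpha = 0.05, tails = 1)
  expect_equal(r85$n_per_group, 59)
  expect_equal(r85$n_total, 118)
  # minimality: one participant fewer misses the power target
  expect_lt(dietddm:::ttest_power(50, 0.5, 0.05, 1, FALSE), 0.80)
  expect_gte(r80$achieved_power, 0.80)
  # achieved power agrees with the stats::power.t.test oracle
  oracle <- power.t.test(n = 51, delta = 0.5, sd = 1, sig.level = 0.05,
                         type = "two.sample",
                         alternative = "one.sided")$power
  expect_equal(r80$achieved_power, oracle, tolerance = 1e-6)
  # n per group never increases with the effect size
  ns <- vapply(c(0.3, 0.5, 0.8, 1.2), function(d)
    sample_size_ttest(d, 0.8, 0.05, 2)$n_per_group, numeric(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(sample_size_ttest(0), "d > 0")
})
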