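test_that("model construction validates its inputs and variants", {
  sh <- shared_small_fit()
  trials <- sh$study$trials
  expect_error(build_ddm_model(trials[0, ]), "empty")
  expect_error(build_ddm_model(trials, variant = "three_weight"))
  expect_error(build_ddm_model(trials, min_trials = 1000), "fewer than")
  bad <- trials
  bad$taste[1] <- 0
  expect_error(build_ddm_model(bad), "coded")
  m <- build_ddm_model(trials, "two_weight")
  expect_s3_class(m, "ddm_model")
  expect_true(m$est_taste && m$est_health)
})

test_that("the two-weight fit declares all five free parameter families", {
  sh <- shared_small_fit()
  hyper <- c("mu_w_taste", "mu_w_health", "mu_bias", "mu_boundary",
             "mu_ndt")
  expect_true(all(hyper %in% sh$fit$parameters))
  expect_true(all(paste0("sigma2_", sub("mu_", "", hyper)) %in%
                    sh$fit$parameters))
})

test_that("single-attribute variants pin the excluded weight to zero", {
  sh <- shared_small_fit()
  m <- build_ddm_model(sh$study$trials, "taste_only")
  fit <- sample_posterior(m, n_chains = 2, n_iter = 60, burn_in = 60,
                          thin = 3, seeds = c(5, 6))
  wh <- c(fit$draws[, , grep("^w_health\\[", fit$parameters,
                             value = TRUE)])
  expect_true(all(wh == 0))
  expect_false("mu_w_health" %in% fit$parameters)
})

test_that("chains are deterministic given their seeds", {
  sh <- shared_small_fit()
  f1 <- sample_posterior(sh$model, n_chains = 2, n_iter = 60, burn_in = 30,
                         thin = 3, seeds = c(7, 8))
  f2 <- sample_posterior(sh$model, n_chains = 2, n_iter = 60, burn_in = 30,
                         thin = 3, seeds = c(7, 8))
  expect_identical(f1$draws, f2$draws)
  expect_error(sample_posterior(sh$model, n_chains = 2, seeds = c(3, 3)),
               "distinct")
})

test_that("with the likelihood disabled every marginal matches its prior", {
  sh <- shared_small_fit()
  fit <- sample_posterior(sh$model, n_chains = 2, n_iter = 2500,
                          burn_in = 0, thin = 1, seeds = c(11, 12),
                          use_likelihood = FALSE)
  draws <- function(p) c(fit$draws[, , p])       # 5000 draws
  expect_gt(ks.test(draws("mu_w_taste"), "punif", -5, 5)$p.value, 0.01)
  expect_gt(ks.test(draws("mu_bias"), "punif", 0, 1)$p.value, 0.01)
  expect_gt(ks.test(draws("mu_ndt"), "punif", 0, 10)$p.value, 0.01)
  expect_gt(ks.test(draws("mu_boundary"), "punif", 0.001, 2)$p.value, 0.01)
  expect_gt(ks.test(draws("sigma2_w_taste"), "pgamma", 1, 0.1)$p.value,
            0.01)
  # population taste weight: mean near 0, range filling (-5, 5)
  expect_lt(abs(mean(draws("mu_w_taste"))), 0.15)
  expect_lt(min(draws("mu_w_taste")), -4.8)
  expect_gt(max(draws("mu_w_taste")), 4.8)
  # subject-level drift variance respects its truncation interval
  s2d <- c(fit$draws[, , grep("^s2d\\[", fit$parameters, value = TRUE)])
  expect_true(all(s2d >= 0.001 & s2d <= 2))
})

test_that("Gelman-Rubin psrf behaves as the variance-ratio formula", {
  set.seed(1)
  # two long chains from one distribution: psrf near 1
  x <- cbind(rnorm(4000), rnorm(4000))
  expect_equal(gelman_rubin(x), 1, tolerance = 0.01)
  # separated chains: psrf far above the 1.1 rule of thumb
  y <- cbind(rnorm(200, 0), rnorm(200, 10))
  expect_gt(gelman_rubin(y), 1.1)
  # agreement with an independently coded evaluation of the formula
  z <- matrix(rnorm(900, sd = 2), ncol = 3)
  n <- nrow(z); m <- ncol(z)
  means <- colMeans(z)
  W <- sum(sweep(z, 2, means)^2) / (m * (n - 1))
  B <- n / (m - 1) * sum((means - mean(z))^2)
  expect_equal(gelman_rubin(z), sqrt(((n - 1) / n * W + B / n) / W),
               tolerance = 1e-10)
  expect_error(gelman_rubin(matrix(1:100, ncol = 1)), "2 chains")
})

test_that("autocorrelation matches known processes", {
  expect_equal(autocorrelation(rnorm(50), 0), 1)
  set.seed(2)
  wn <- rnorm(5000)
  expect_lt(abs(autocorrelation(wn, 100)), 2 / sqrt(5000))
  # AR(1): acf at lag k decays like phi^k
  phi <- 0.9
  ar <- as.numeric(arima.sim(list(ar = phi), 20000))
  for (k in c(1, 5, 10))
    expect_lt(abs(autocorrelation(ar, k) - phi^k), 0.05)
  expect_warning(a0 <- autocorrelation(rep(3, 50), 2), "constant")
  expect_equal(a0, 0)
})

test_that("deviance recomputation matches stored values and hand sums", {
  sh <- shared_small_fit()
  fit <- sample_posterior(sh$model, n_chains = 2, n_iter = 30, burn_in = 30,
                          thin = 3, seeds = c(41, 42))
  dev <- deviance_samples(fit)
  expect_equal(dev, c(fit$draws[, , "deviance"]), tolerance = 1e-8)
  # hand computation on a 3-trial fixture at one retained draw, using the
  # R-level density as an independent route to the likelihood
  tr3 <- sh$study$trials[1:3, ]
  id <- tr3$participant_id[1]
  tr3$participant_id <- id
  m3 <- build_ddm_model(tr3, "two_weight", min_trials = 3)
  f3 <- sample_posterior(m3, n_chains = 2, n_iter = 9, burn_in = 9,
                         thin = 3, seeds = c(1, 2))
  d <- f3$draws[1, 1, ]
  gh <- dietddm:::gauss_hermite_rule(9)
  dens_one <- function(rt, td, hd) {
    v <- d[["w_taste[1]"]] * td + d[["w_health[1]"]] * hd +
      sqrt(2 * d[["s2d[1]"]]) * gh$x
    sum(gh$w / sqrt(pi) * vapply(v, function(vk)
      fpt_density(abs(rt), if (rt > 0) "upper" else "lower",
                  wiener_params(d[["boundary[1]"]], d[["bias[1]"]], vk,
                                d[["ndt[1]"]])), numeric(1)))
  }
  hand <- -2 * sum(log(mapply(dens_one, tr3$rt_signed, tr3$taste,
                              tr3$health)))
  expect_equal(f3$draws[1, 1, "deviance"], hand, tolerance = 1e-6,
               ignore_attr = TRUE)
  # participant mismatch is caught
  other <- sh$study$trials
  other$participant_id <- other$participant_id + 1000
  expect_error(deviance_samples(fit, other), "do not match")
})
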