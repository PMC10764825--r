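#' Per-subject valuation regression
#'
#' Ordinary least-squares fit of the 4-point stimulus-value rating on
#' mean-centered healthiness (HR) and tastiness (TR) ratings, a mean-
#' centered trial-index regressor for fatigue, and the three interactions
#' HR x TR, HR x trial and TR x trial.
#'
#' @param trials trial table for one participant with columns `sv`,
#'   `taste`, `health`, `trial_index` (>= 10 rows).
#' @return data.frame row of class `valuation_betas` with the intercept
#'   and six slope coefficients.
#' @export
valuation_glm <- function(trials) {
  stopifnot(all(c("sv", "taste", "health", "trial_index") %in% names(trials)))
  if (nrow(trials) < 10)
    stop("valuation regression needs at least 10 trials")
  d <- data.frame(
    sv = trials$sv,
    HR = trials$health - mean(trials$health),
    TR = trials$taste - mean(trials$taste),
    trial = trials$trial_index - mean(trials$trial_index)
  )
  fit <- stats::lm(sv ~ HR + TR + trial + HR:TR + HR:trial + TR:trial,
                   data = d)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient valuation design matrix; participant excluded")
  cf <- stats::coef(fit)
  out <- data.frame(
    participant_id = if ("participant_id" %in% names(trials))
      trials$participant_id[1] else NA,
    beta0 = cf[["(Intercept)"]], beta_HR = cf[["HR"]], beta_TR = cf[["TR"]],
    beta_trial = cf[["trial"]], beta_HRxTR = cf[["HR:TR"]],
    beta_HRxtrial = cf[["HR:trial"]], beta_TRxtrial = cf[["TR:trial"]],
    stringsAsFactors = FALSE)
  class(out) <- c("valuation_betas", class(out))
  out
}

#' Second-level random-effects t-tests on valuation coefficients
#'
#' One-sample t-tests of each coefficient against zero within each group,
#' plus two-sample two-tailed t-tests between every pair of groups.
#'
#' @param betas_by_group named list of `valuation_betas` tables (rows =
#'   participants), one per group with >= 2 participants.
#' @return data.frame with columns `coefficient`, `test`, `group_a`,
#'   `group_b`, `estimate`, `t`, `df`, `p`.
#' @export
second_level_ttests <- function(betas_by_group) {
  stopifnot(is.list(betas_by_group), length(betas_by_group) >= 1)
  ns <- vapply(betas_by_group, nrow, integer(1))
  if (any(ns < 2)) stop("every group needs at least 2 participants")
  coef_cols <- c("beta0", "beta_HR", "beta_TR", "beta_trial", "beta_HRxTR",
                 "beta_HRxtrial", "beta_TRxtrial")
  rows <- list()
  for (g in names(betas_by_group)) {
    for (cc in coef_cols) {
      tt <- stats::t.test(betas_by_group[[g]][[cc]])
      rows[[length(rows) + 1L]] <- data.frame(
        coefficient = cc, test = "one_sample", group_a = g, group_b = NA,
        estimate = unname(tt$estimate), t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value, stringsAsFactors = FALSE)
    }
  }
  groups <- names(betas_by_group)
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2)
    for (i in seq_len(ncol(pairs))) {
      a <- pairs[1, i]; b <- pairs[2, i]
      for (cc in coef_cols) {
        tt <- stats::t.test(betas_by_group[[a]][[cc]],
                            betas_by_group[[b]][[cc]], var.equal = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          coefficient = cc, test = "two_sample", group_a = a, group_b = b,
          estimate = unname(diff(rev(tt$estimate))), t = unname(tt$statistic),
          df = unname(tt$parameter), p = tt$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Calorie median split for one participant
#'
#' Labels each trial `low` if its calorie density is at or below the
#' participant's median and `high` otherwise (ties go to `low`).
#'
#' @param calorie_density numeric vector of positive densities with at
#'   least 2 distinct values.
#' @return Factor of labels `low`/`high`, one per trial.
#' @export
calorie_median_split <- function(calorie_density) {
  stopifnot(is.numeric(calorie_density), all(calorie_density > 0))
  if (length(unique(calorie_density)) < 2)
    stop("median split needs at least 2 distinct calorie densities")
  med <- stats::median(calorie_density)
  factor(ifelse(calorie_density <= med, "low", "high"),
         levels = c("low", "high"))
}

#' Fisher r-to-z contrast of two independent correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-tailed p-value from the standard normal.
#'
#' @param r1,r2 correlations, strictly inside (-1, 1).
#' @param n1,n2 sample sizes (> 3).
#' @return list with `z` and two-tailed `p`.
#' @export
fisher_r_to_z <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, n1 > 3, n2 > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Composite hunger score
#'
#' Arithmetic mean of the three 7-point hunger ratings (overall,
#' homeostatic and hedonic hunger).
#'
#' @param ratings numeric vector of exactly three values in [1, 7].
#' @return The mean score.
#' @export
composite_hunger <- function(ratings) {
  if (length(ratings) != 3)
    stop("composite hunger score requires exactly three ratings")
  if (any(ratings < 1 | ratings > 7))
    stop("hunger ratings must lie on the 7-point scale [1, 7]")
  mean(ratings)
}

# Noncentral-t power of the two-sample (or paired) t-test at n per group.
ttest_power <- function(n, d, alpha, tails, paired) {
  if (paired) {
    df <- n - 1
    ncp <- d * sqrt(n)
  } else {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
  }
  if (df < 1) return(0)
  if (tails == 1) {
    crit <- stats::qt(1 - alpha, df)
    1 - stats::pt(crit, df, ncp)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
  }
}

#' A-priori sample size for a t-test
#'
#' Smallest integer group size n such that the noncentral-t power of the
#' two-sample (or paired) t-test at effect size d reaches the requested
#' power.
#'
#' @param d Cohen's d (> 0).
#' @param power requested power in (0, 1).
#' @param alpha type-I error rate in (0, 1).
#' @param tails 1 (one-tailed) or 2 (two-tailed).
#' @param paired paired design (default FALSE: two independent samples).
#' @return list with `n_per_group`, `n_total`, `achieved_power`.
#' @export
sample_size_ttest <- function(d, power = 0.80, alpha = 0.05, tails = 1,
                              paired = FALSE) {
  stopifnot(d > 0, power > 0, power < 1, alpha > 0, alpha < 1,
            tails %in% c(1, 2))
  n <- 2
  while (ttest_power(n, d, alpha, tails, paired) < power) {
    n <- n + 1
    if (n > 1e6) stop("requested power unattainable at this effect size")
  }
  list(n_per_group = n, n_total = if (paired) n else 2 * n,
       achieved_power = ttest_power(n, d, alpha, tails, paired))
}
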