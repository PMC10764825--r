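#' Fit single-level mediation path coefficients
#'
#' Three-variable mediation of a binary group code X (+1/-1) on an outcome
#' Y through a mediator M, by ordinary least squares: path a from the
#' regression of M on X; paths b and c' (direct effect) from the joint
#' regression of Y on M and X; total effect c from the regression of Y on
#' X.  The indirect effect is `a * b`, which equals `c - c'` exactly for
#' OLS on a common sample.
#'
#' @param records data.frame with columns `X` (values -1/+1, both levels
#'   present), `M`, `Y`; at least 4 rows.
#' @param standardize z-score M and Y before fitting (default FALSE).
#' @return list of class `mediation_fit` with elements `a`, `b`, `c`,
#'   `c_prime`, `ab`, `n`.
#' @export
fit_mediation_paths <- function(records, standardize = FALSE) {
  stopifnot(all(c("X", "M", "Y") %in% names(records)))
  if (nrow(records) < 4) stop("mediation needs at least 4 records")
  if (!all(records$X %in% c(-1, 1)))
    stop("group code X must be -1 or +1")
  if (length(unique(records$X)) < 2)
    stop("both group levels must be present")
  if (stats::var(records$M) == 0) stop("mediator M is constant")
  if (standardize) {
    records$M <- as.vector(scale(records$M))
    records$Y <- as.vector(scale(records$Y))
  }
  a <- stats::coef(stats::lm(M ~ X, data = records))[["X"]]
  yb <- stats::coef(stats::lm(Y ~ M + X, data = records))
  cc <- stats::coef(stats::lm(Y ~ X, data = records))[["X"]]
  structure(list(a = a, b = yb[["M"]], c = cc, c_prime = yb[["X"]],
                 ab = a * yb[["M"]], n = nrow(records)),
            class = "mediation_fit")
}

# Closed-form path coefficients from sufficient statistics, vectorized over
# bootstrap resamples (rows of the statistics matrix).  Used internally by
# the bootstrap so 10,000 refits stay fast.
paths_from_stats <- function(s, n) {
  mx <- s[, "x"] / n; mm <- s[, "m"] / n; my <- s[, "y"] / n
  sxx <- s[, "xx"] / n - mx^2
  smm <- s[, "mm"] / n - mm^2
  sxm <- s[, "xm"] / n - mx * mm
  sxy <- s[, "xy"] / n - mx * my
  smy <- s[, "my"] / n - mm * my
  a <- sxm / sxx
  cc <- sxy / sxx
  det <- smm * sxx - sxm^2
  b <- (smy * sxx - sxy * sxm) / det
  c_prime <- (sxy * smm - smy * sxm) / det
  cbind(a = a, b = b, c = cc, c_prime = c_prime, ab = a * b)
}

#' Bootstrap inference for the mediation paths
#'
#' Resamples the raw observations with replacement `n_boot` times, refits
#' all path coefficients per resample, and reports percentile two-tailed
#' p-values `2 * min(P(path <= 0), P(path >= 0))` together with bootstrap
#' SEs and 95% percentile intervals.  Records are canonically ordered
#' before resampling so results are invariant to input row order;
#' resamples with a single group level are redrawn and counted.
#'
#' @param records as in [fit_mediation_paths()].
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param seed integer seed; resampling is deterministic given it.
#' @param p_method `"percentile"` (default) or `"normal"`
#'   (z = estimate / bootstrap SE).
#' @param standardize z-score M and Y before fitting.
#' @param roi optional ROI label carried into the result.
#' @return list of class `mediation_result`: point estimates, per-path
#'   `se`, `p`, `ci_lower`, `ci_upper`, plus `n_boot`, `seed`,
#'   `n_degenerate_redrawn`, `roi`.
#' @export
bootstrap_mediation <- function(records, n_boot = 10000, seed = 1L,
                                p_method = c("percentile", "normal"),
                                standardize = FALSE, roi = NA_character_) {
  p_method <- match.arg(p_method)
  point <- fit_mediation_paths(records, standardize = standardize)
  if (standardize) {
    records$M <- as.vector(scale(records$M))
    records$Y <- as.vector(scale(records$Y))
  }
  # canonical order: bootstrap output depends only on the record set
  records <- records[order(records$X, records$M, records$Y), , drop = FALSE]
  n <- nrow(records)
  feats <- cbind(x = records$X, m = records$M, y = records$Y,
                 xx = records$X^2, mm = records$M^2,
                 xm = records$X * records$M, xy = records$X * records$Y,
                 my = records$M * records$Y)
  set.seed(seed)
  n_degenerate <- 0L
  draw_stats <- function(k) {
    counts <- stats::rmultinom(k, n, rep(1 / n, n))    # n x k
    s <- t(counts) %*% feats
    colnames(s) <- colnames(feats)
    s
  }
  s <- draw_stats(n_boot)
  # a resample with one group level (zero X variance) or a collinear
  # X/M pair cannot be refit: redraw those
  repeat {
    sxx <- s[, "xx"] / n - (s[, "x"] / n)^2
    smm <- s[, "mm"] / n - (s[, "m"] / n)^2
    sxm <- s[, "xm"] / n - (s[, "x"] / n) * (s[, "m"] / n)
    bad <- which(sxx <= 0 | smm * sxx - sxm^2 <= 1e-12 * pmax(smm * sxx, 1))
    if (!length(bad)) break
    n_degenerate <- n_degenerate + length(bad)
    s[bad, ] <- draw_stats(length(bad))
  }
  boot <- paths_from_stats(s, n)
  est <- c(a = point$a, b = point$b, c = point$c, c_prime = point$c_prime,
           ab = point$ab)
  se <- apply(boot, 2, stats::sd)
  p <- switch(p_method,
    percentile = vapply(colnames(boot), function(j)
      min(1, 2 * min(mean(boot[, j] <= 0), mean(boot[, j] >= 0))),
      numeric(1)),
    normal = 2 * stats::pnorm(-abs(est / se))
  )
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
  structure(list(estimates = est, se = se, p = p,
                 ci_lower = ci[1, ], ci_upper = ci[2, ],
                 n = n, n_boot = n_boot, seed = seed,
                 p_method = p_method,
                 n_degenerate_redrawn = n_degenerate, roi = roi),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("bootstrap mediation (%s, n = %d, %d resamples)\n",
              ifelse(is.na(x$roi), "unlabelled ROI", x$roi), x$n, x$n_boot))
  tab <- data.frame(estimate = x$estimates, se = x$se, p = x$p,
                    ci_lower = x$ci_lower, ci_upper = x$ci_upper)
  print(round(tab, 4))
  invisible(x)
}

#' Bonferroni correction gate
#'
#' Threshold `alpha / m` for m comparisons, reported both exactly and
#' rounded to 2 decimals (the reporting convention for 0.05/3 -> 0.02),
#' with each p-value compared against the exact threshold.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param m number of comparisons (default 3 ROIs).
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `threshold`, `threshold_reported`, and logical
#'   `significant` per p-value.
#' @export
bonferroni_gate <- function(p_values, m = 3, alpha = 0.05) {
  stopifnot(m >= 1)
  if (any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  thr <- alpha / m
  list(threshold = thr, threshold_reported = round(thr, 2),
       significant = p_values < thr)
}
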