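#' Deviance information criterion
#'
#' `DIC = mean(deviance) + 0.5 * var(deviance)`, with the half-variance of
#' the posterior deviance acting as the effective-parameter penalty
#' (Gelman-style definition).  The sample (n - 1) variance is used.
#'
#' @param deviance_samples numeric vector of per-draw deviances (>= 2).
#' @return DIC value (lower indicates better fit).
#' @export
dic <- function(deviance_samples) {
  if (length(deviance_samples) < 2)
    stop("DIC needs at least 2 deviance draws")
  mean(deviance_samples) + 0.5 * stats::var(deviance_samples)
}

#' Rank model variants by DIC
#'
#' @param dic_by_variant named numeric vector of DIC values, one per model
#'   variant (distinct names required).
#' @return data.frame sorted by ascending DIC with columns `variant`,
#'   `dic`, `delta_dic` and logical `preferred` (lowest DIC).
#' @export
compare_models <- function(dic_by_variant) {
  if (length(dic_by_variant) < 2)
    stop("model comparison needs at least 2 variants")
  if (is.null(names(dic_by_variant)) ||
      anyDuplicated(names(dic_by_variant)) || any(names(dic_by_variant) == ""))
    stop("variants must have unique non-empty names")
  ord <- order(dic_by_variant)
  d <- dic_by_variant[ord]
  data.frame(variant = names(d), dic = unname(d),
             delta_dic = unname(d - d[1]),
             preferred = seq_along(d) == 1L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Element-wise posterior difference between two groups' chains
#'
#' Concatenates each group's retained chains for one parameter (paired by
#' draw index) and returns the element-wise A - B differences.  Unequal
#' retained lengths are truncated to the common minimum with a warning.
#'
#' @param chains_a,chains_b `ddm_chains` objects (or plain numeric vectors
#'   of already-concatenated draws).
#' @param parameter parameter name, e.g. `"mu_w_taste"`.
#' @return Numeric vector of per-draw differences.
#' @export
posterior_difference <- function(chains_a, chains_b, parameter = NULL) {
  a <- if (inherits(chains_a, "ddm_chains"))
    concat_chains(chains_a, parameter) else as.numeric(chains_a)
  b <- if (inherits(chains_b, "ddm_chains"))
    concat_chains(chains_b, parameter) else as.numeric(chains_b)
  if (length(a) != length(b)) {
    warning(sprintf(
      "retained lengths differ (%d vs %d); truncating to the common minimum",
      length(a), length(b)))
    n <- min(length(a), length(b))
    a <- a[seq_len(n)]
    b <- b[seq_len(n)]
  }
  a - b
}

#' Posterior probability of a directional group difference
#'
#' `PP` is the proportion of posterior-difference draws strictly satisfying
#' the stated direction (draws exactly at zero count against it), and
#' `p_mcmc = 1 - PP` is the complementary Bayesian "p-value".
#'
#' @param diff_samples numeric vector of per-draw differences (A - B).
#' @param direction `"greater"` (A > B) or `"less"`.
#' @param parameter optional label carried into the result.
#' @return A list of class `group_contrast`: `parameter`, `direction`,
#'   `mean_diff`, `PP`, `p_mcmc`, `n_draws`.
#' @export
posterior_probability <- function(diff_samples,
                                  direction = c("greater", "less"),
                                  parameter = NA_character_) {
  direction <- match.arg(direction)
  if (length(diff_samples) == 0) stop("empty difference sample")
  pp <- if (direction == "greater") mean(diff_samples > 0)
        else mean(diff_samples < 0)
  structure(list(parameter = parameter, direction = direction,
                 mean_diff = mean(diff_samples), PP = pp,
                 p_mcmc = 1 - pp, n_draws = length(diff_samples)),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("contrast %s (%s): mean diff = %.4f, PP = %.3f, p_mcmc = %.3f (%d draws)\n",
              x$parameter, x$direction, x$mean_diff, x$PP, x$p_mcmc,
              x$n_draws))
  invisible(x)
}

#' Group-contrast table for fitted groups
#'
#' Computes posterior-probability contrasts between pairs of fitted groups
#' for the population-level parameters, using each contrast's prior
#' predicted direction (taste weight, bias: increased > decreased and
#' control > decreased; health weight reversed).
#'
#' @param fits named list of `ddm_chains`, one per group (names are group
#'   labels, e.g. `decreased`, `control`, `increased`).
#' @param parameters population-level parameters to contrast.
#' @param directions optional named list `parameter -> direction` for the
#'   A - B difference; defaults to `"greater"` except `mu_w_health`, which
#'   is `"less"` for contrasts of hungrier vs less-hungry suggestions.
#' @param pairs 2-column character matrix of group pairs (A, B); default
#'   all ordered pairs (increased, decreased), (control, decreased),
#'   (increased, control) present in `fits`.
#' @return data.frame: `parameter`, `group_a`, `group_b`, `mean_diff`,
#'   `PP`, `p_mcmc`, `direction`.
#' @export
group_contrast_table <- function(fits,
                                 parameters = c("mu_w_taste", "mu_w_health",
                                                "mu_bias"),
                                 directions = NULL, pairs = NULL) {
  stopifnot(is.list(fits), length(fits) >= 2, !is.null(names(fits)))
  if (is.null(pairs)) {
    cand <- rbind(c("increased", "decreased"), c("control", "decreased"),
                  c("increased", "control"))
    pairs <- cand[cand[, 1] %in% names(fits) & cand[, 2] %in% names(fits), ,
                  drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    for (par in parameters) {
      if (!par %in% fits[[a]]$parameters) next
      dir <- if (!is.null(directions) && !is.null(directions[[par]]))
        directions[[par]]
      else if (par == "mu_w_health") "less" else "greater"
      d <- posterior_difference(fits[[a]], fits[[b]], par)
      ct <- posterior_probability(d, dir, parameter = par)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, group_a = a, group_b = b,
        mean_diff = ct$mean_diff, PP = ct$PP, p_mcmc = ct$p_mcmc,
        direction = dir, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
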