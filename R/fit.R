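#' Build a hierarchical diffusion-model specification
#'
#' Declares the hierarchical Bayesian two-attribute drift-diffusion model
#' (or one of its single-attribute variants) for a trial table.  Five free
#' parameter families (boundary, starting bias, taste weight, health
#' weight, non-decision time) receive participant-level random effects with
#' the stated hyper-priors; the inter-trial drift variance gets a truncated
#' gamma prior per participant.  Single-attribute variants fix the excluded
#' weight to zero.
#'
#' Priors: attribute-weight hyper-means Uniform(-5, 5); starting-bias
#' hyper-mean Uniform(0, 1); boundary hyper-mean Uniform(0.001, 2) with the
#' subject boundary capped at 2; non-decision-time hyper-mean
#' Uniform(0, 10); every hyper-variance Gamma(shape 1, rate 0.1); drift
#' variance Gamma(1, 0.1) truncated to [0.001, 2].
#'
#' @param trials trial table with columns `participant_id`, `taste`,
#'   `health`, `rt_signed` (positive = "yes").
#' @param variant `"two_weight"`, `"taste_only"` or `"health_only"`.
#' @param min_trials minimum trials per participant (default 10).
#' @param fix_boundary if non-NULL, fixes every participant's boundary to
#'   this value instead of estimating it.
#' @param gh_nodes Gauss-Hermite nodes for marginalizing inter-trial drift
#'   variability (default 9).
#' @return A list of class `ddm_model`.
#' @export
build_ddm_model <- function(trials,
                            variant = c("two_weight", "taste_only",
                                        "health_only"),
                            min_trials = 10, fix_boundary = NULL,
                            gh_nodes = 9) {
  variant <- match.arg(variant)
  required <- c("participant_id", "taste", "health", "rt_signed")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols))
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(trials) == 0L) stop("empty trial table")
  check_rating_codes(trials$taste, "taste")
  check_rating_codes(trials$health, "health")
  if (any(trials$rt_signed == 0)) stop("signed response times must be non-zero")
  ids <- unique(trials$participant_id)
  data <- lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id, , drop = FALSE]
    list(rt = tr$rt_signed, td = tr$taste, hd = tr$health)
  })
  n_tr <- vapply(data, function(d) length(d$rt), integer(1))
  if (any(n_tr < min_trials))
    stop(sprintf("participant(s) %s have fewer than %d trials",
                 paste(ids[n_tr < min_trials], collapse = ", "), min_trials))
  structure(list(
    data = data, participant_ids = ids, n_subjects = length(ids),
    variant = variant,
    est_taste = variant != "health_only",
    est_health = variant != "taste_only",
    fix_boundary = fix_boundary,
    gh = gauss_hermite_rule(gh_nodes),
    min_rt = vapply(data, function(d) min(abs(d$rt)), numeric(1))
  ), class = "ddm_model")
}

# Family table: subject-level truncation bounds and hyper-mean prior range.
ddm_families <- function(model) {
  fam <- list(
    w_taste  = list(lo = -5, hi = 5, mu_lo = -5, mu_hi = 5,
                    est = model$est_taste),
    w_health = list(lo = -5, hi = 5, mu_lo = -5, mu_hi = 5,
                    est = model$est_health),
    bias     = list(lo = 0.001, hi = 0.999, mu_lo = 0, mu_hi = 1,
                    est = TRUE),
    boundary = list(lo = 0.001, hi = 2, mu_lo = 0.001, mu_hi = 2,
                    est = is.null(model$fix_boundary)),
    ndt      = list(lo = 0, hi = 10, mu_lo = 0, mu_hi = 10, est = TRUE)
  )
  fam
}

# log density of the truncated normal on (lo, hi)
ldtnorm <- function(x, mu, sd, lo, hi) {
  z <- stats::pnorm(hi, mu, sd) - stats::pnorm(lo, mu, sd)
  if (z <= 0) return(-Inf)
  stats::dnorm(x, mu, sd, log = TRUE) - log(z)
}

# log density of the Gamma(1, 0.1) prior truncated to [0.001, 2]
ld_s2d_prior <- function(x) {
  z <- stats::pgamma(2, 1, 0.1) - stats::pgamma(0.001, 1, 0.1)
  stats::dgamma(x, 1, 0.1, log = TRUE) - log(z)
}

subject_loglik <- function(model, p, th, floor_val) {
  d <- model$data[[p]]
  ddm_loglik_sum(d$rt, d$td, d$hd, th[["w_taste"]], th[["w_health"]],
                 th[["bias"]], th[["boundary"]], th[["ndt"]], th[["s2d"]],
                 model$gh$x, model$gh$w, floor_val)
}

# One ancestral draw of (hyper, theta) from the prior
prior_draw <- function(model) {
  fam <- ddm_families(model)
  P <- model$n_subjects
  hyper <- c()
  theta <- matrix(0, P, 6,
                  dimnames = list(NULL, c("w_taste", "w_health", "bias",
                                          "boundary", "ndt", "s2d")))
  for (f in names(fam)) {
    fi <- fam[[f]]
    if (!fi$est) {
      theta[, f] <- if (f == "boundary" && !is.null(model$fix_boundary))
        model$fix_boundary else 0
      next
    }
    mu <- stats::runif(1, fi$mu_lo, fi$mu_hi)
    s2 <- stats::rgamma(1, 1, 0.1)
    hyper[paste0("mu_", f)] <- mu
    hyper[paste0("sigma2_", f)] <- s2
    theta[, f] <- rtnorm(P, mu, sqrt(s2), fi$lo, fi$hi)
  }
  # truncated-gamma prior draw for the drift variance, by inverse CDF
  plo <- stats::pgamma(0.001, 1, 0.1)
  phi <- stats::pgamma(2, 1, 0.1)
  theta[, "s2d"] <- stats::qgamma(plo + stats::runif(P) * (phi - plo), 1, 0.1)
  list(hyper = hyper, theta = theta)
}

#' Sample the posterior of a hierarchical diffusion model
#'
#' Adaptive Metropolis-within-Gibbs sampler: scalar random-walk updates of
#' every subject-level parameter (with the Wiener first-passage likelihood
#' marginalized over inter-trial drift variability by Gauss-Hermite
#' quadrature) and of every hyper-parameter, with proposal scales adapted
#' toward 44% acceptance during burn-in and frozen afterwards.  Chains are
#' deterministic given their seeds.  With `use_likelihood = FALSE` the
#' target collapses to the prior and the sampler draws i.i.d. from it
#' (independence proposals from the prior are then always accepted), which
#' is the configuration used for prior-recovery checks.
#'
#' @param model a [build_ddm_model()] specification.
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_iter post-burn-in iterations per chain.
#' @param burn_in adaptation/burn-in iterations discarded from the front.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param seeds integer vector of distinct per-chain seeds; default
#'   `1000 * (1:n_chains) + 7`.
#' @param use_likelihood set FALSE to sample from the priors only.
#' @param floor_value log-likelihood floor for zero-density proposals.
#' @param init_retries maximum redraws of initial values when the starting
#'   log-posterior is degenerate.
#' @return A `ddm_chains` object: `draws` is an array
#'   (iteration x chain x parameter) including a `deviance` column.
#' @export
sample_posterior <- function(model, n_chains = 3, n_iter = 3000,
                             burn_in = 1500, thin = 3, seeds = NULL,
                             use_likelihood = TRUE, floor_value = -1e10,
                             init_retries = 100) {
  stopifnot(inherits(model, "ddm_model"), n_chains >= 2, n_iter >= thin)
  if (is.null(seeds)) seeds <- 1000L * seq_len(n_chains) + 7L
  if (length(seeds) != n_chains || anyDuplicated(seeds))
    stop("need one distinct seed per chain")
  chains <- lapply(seeds, function(s)
    run_ddm_chain(model, n_iter, burn_in, thin, s, use_likelihood,
                  floor_value, init_retries))
  par_names <- colnames(chains[[1]])
  kept <- nrow(chains[[1]])
  draws <- array(NA_real_, c(kept, n_chains, length(par_names)),
                 dimnames = list(NULL, paste0("chain", seq_len(n_chains)),
                                 par_names))
  for (k in seq_len(n_chains)) draws[, k, ] <- chains[[k]]
  structure(list(draws = draws, parameters = par_names, seeds = seeds,
                 n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, variant = model$variant,
                 participant_ids = model$participant_ids, model = model,
                 use_likelihood = use_likelihood),
            class = "ddm_chains")
}

run_ddm_chain <- function(model, n_iter, burn_in, thin, seed,
                          use_likelihood, floor_val, init_retries) {
  set.seed(seed)
  fam <- ddm_families(model)
  P <- model$n_subjects
  subj_cols <- c("w_taste", "w_health", "bias", "boundary", "ndt", "s2d")
  est_cols <- c(names(fam)[vapply(fam, `[[`, TRUE, "est")], "s2d")
  hyper_names <- as.vector(rbind(paste0("mu_", setdiff(est_cols, "s2d")),
                                 paste0("sigma2_", setdiff(est_cols, "s2d"))))
  par_names <- c(hyper_names,
                 as.vector(vapply(subj_cols, function(f)
                   sprintf("%s[%d]", f, seq_len(P)), character(P))),
                 "deviance")
  kept <- n_iter %/% thin
  out <- matrix(NA_real_, kept, length(par_names),
                dimnames = list(NULL, par_names))

  record <- function(row, hyper, theta, dev) {
    out[row, hyper_names] <<- hyper[hyper_names]
    for (f in subj_cols)
      out[row, sprintf("%s[%d]", f, seq_len(P))] <<- theta[, f]
    out[row, "deviance"] <<- dev
  }

  if (!use_likelihood) {
    # exact i.i.d. prior sampling (independence MH against the prior)
    for (i in seq_len(kept)) {
      st <- prior_draw(model)
      record(i, st$hyper, st$theta, NA_real_)
    }
    return(out)
  }

  # --- initialization: prior draws; ndt started below each subject's
  # minimum |rt| so no trial starts in the floored region ---
  for (attempt in seq_len(init_retries)) {
    st <- prior_draw(model)
    st$theta[, "ndt"] <- stats::runif(P, 0.1, 0.9) * model$min_rt
    ll <- vapply(seq_len(P), function(p)
      subject_loglik(model, p, st$theta[p, ], floor_val), numeric(1))
    if (all(ll > floor_val / 2)) break
    if (attempt == init_retries)
      stop("could not find a finite-likelihood initialization")
  }
  hyper <- st$hyper
  theta <- st$theta
  ls_subj <- matrix(log(0.25), P, 6, dimnames = list(NULL, subj_cols))
  ls_hyper <- stats::setNames(rep(log(0.25), length(hyper_names)),
                              hyper_names)

  subj_prior_term <- function(f, x, hyper) {
    if (f == "s2d") return(ld_s2d_prior(x))
    fi <- fam[[f]]
    if (!fi$est) return(0)
    ldtnorm(x, hyper[[paste0("mu_", f)]],
            sqrt(hyper[[paste0("sigma2_", f)]]), fi$lo, fi$hi)
  }
  fam_sum <- function(f, mu, s2) {
    fi <- fam[[f]]
    sum(vapply(theta[, f], ldtnorm, numeric(1), mu = mu, sd = sqrt(s2),
               lo = fi$lo, hi = fi$hi))
  }

  upd_cols <- intersect(subj_cols, est_cols)
  total <- burn_in + n_iter
  row <- 0L
  for (iter in seq_len(total)) {
    rate <- if (iter <= burn_in) min(0.1, 1 / sqrt(iter)) else 0
    # subject-level scalar updates
    for (p in seq_len(P)) {
      for (f in upd_cols) {
        cur <- theta[p, f]
        prop <- cur + exp(ls_subj[p, f]) * stats::rnorm(1)
        lo <- if (f == "s2d") 0.001 else fam[[f]]$lo
        hi <- if (f == "s2d") 2 else fam[[f]]$hi
        if (prop <= lo || prop >= hi) {
          ls_subj[p, f] <- ls_subj[p, f] - rate * 0.44
          next
        }
        th_new <- theta[p, ]
        th_new[f] <- prop
        ll_new <- subject_loglik(model, p, th_new, floor_val)
        d <- (ll_new - ll[p]) +
          subj_prior_term(f, prop, hyper) - subj_prior_term(f, cur, hyper)
        alpha <- min(1, exp(d))
        if (stats::runif(1) < alpha) {
          theta[p, f] <- prop
          ll[p] <- ll_new
        }
        ls_subj[p, f] <- ls_subj[p, f] + rate * (alpha - 0.44)
      }
    }
    # hyper-parameter updates (no likelihood term)
    for (f in setdiff(est_cols, "s2d")) {
      fi <- fam[[f]]
      mu_name <- paste0("mu_", f)
      s2_name <- paste0("sigma2_", f)
      # hyper-mean: random walk within its uniform prior range
      cur <- hyper[[mu_name]]
      prop <- cur + exp(ls_hyper[[mu_name]]) * stats::rnorm(1)
      if (prop > fi$mu_lo && prop < fi$mu_hi) {
        d <- fam_sum(f, prop, hyper[[s2_name]]) -
          fam_sum(f, cur, hyper[[s2_name]])
        alpha <- min(1, exp(d))
        if (stats::runif(1) < alpha) hyper[[mu_name]] <- prop
        ls_hyper[[mu_name]] <- ls_hyper[[mu_name]] + rate * (alpha - 0.44)
      } else {
        ls_hyper[[mu_name]] <- ls_hyper[[mu_name]] - rate * 0.44
      }
      # hyper-variance: random walk on the log scale (gamma prior as stated)
      cur <- hyper[[s2_name]]
      prop <- exp(log(cur) + exp(ls_hyper[[s2_name]]) * stats::rnorm(1))
      d <- fam_sum(f, hyper[[mu_name]], prop) -
        fam_sum(f, hyper[[mu_name]], cur) +
        stats::dgamma(prop, 1, 0.1, log = TRUE) -
        stats::dgamma(cur, 1, 0.1, log = TRUE) +
        log(prop) - log(cur)                       # Jacobian
      alpha <- if (is.finite(d)) min(1, exp(d)) else 0
      if (stats::runif(1) < alpha) hyper[[s2_name]] <- prop
      ls_hyper[[s2_name]] <- ls_hyper[[s2_name]] + rate * (alpha - 0.44)
    }
    if (iter > burn_in && (iter - burn_in) %% thin == 0) {
      row <- row + 1L
      record(row, hyper, theta, -2 * sum(ll))
    }
  }
  out
}

#' @export
print.ddm_chains <- function(x, ...) {
  cat(sprintf(
    "hierarchical DDM posterior (%s): %d participants, %d chains x %d retained draws\n",
    x$variant, length(x$participant_ids), x$n_chains, dim(x$draws)[1]))
  cat(sprintf("  iterations %d after burn-in %d, thinning %d; seeds %s\n",
              x$n_iter, x$burn_in, x$thin,
              paste(x$seeds, collapse = ", ")))
  if (isTRUE(x$use_likelihood)) {
    pt <- psrf_table(x)
    cat(sprintf("  max psrf %.4f over %d parameters\n", max(pt$psrf),
                nrow(pt)))
  } else {
    cat("  prior-only draws (likelihood disabled)\n")
  }
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic psrf from between- and within-chain variances: with m chains of
#' length n, `W` the mean within-chain variance and `B/n` the between-chain
#' variance of the chain means, the pooled posterior-variance estimate is
#' `(n-1)/n W + B/n` and psrf is the square root of its ratio to `W`.
#'
#' @param x matrix of samples for a single parameter, iterations in rows
#'   and chains in columns (>= 2 chains, >= 10 iterations).
#' @return psrf (a scalar >= ~1 up to sampling noise).
#' @export
gelman_rubin <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("gelman_rubin needs at least 2 chains")
  if (nrow(x) < 10) stop("gelman_rubin needs at least 10 iterations")
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Per-parameter psrf table for a fitted model
#'
#' @param chains a `ddm_chains` object.
#' @param include_deviance also report the deviance psrf (default FALSE,
#'   matching the convention of reporting it separately).
#' @return data.frame with columns `parameter`, `psrf`.
#' @export
psrf_table <- function(chains, include_deviance = FALSE) {
  stopifnot(inherits(chains, "ddm_chains"))
  pars <- chains$parameters
  if (!include_deviance) pars <- setdiff(pars, "deviance")
  psrf <- vapply(pars, function(p) gelman_rubin(chains$draws[, , p]),
                 numeric(1))
  data.frame(parameter = pars, psrf = unname(psrf),
             stringsAsFactors = FALSE)
}

#' Sample autocorrelation of a chain at a given lag
#'
#' @param chain numeric vector of samples.
#' @param lag non-negative integer lag smaller than the chain length.
#' @return Autocorrelation (1 at lag 0; 0 with a warning for a constant
#'   chain at positive lags).
#' @export
autocorrelation <- function(chain, lag) {
  stopifnot(lag >= 0, lag < length(chain))
  if (lag == 0) return(1)
  if (stats::var(chain) == 0) {
    warning("constant chain: autocorrelation undefined, returning 0")
    return(0)
  }
  drop(stats::acf(chain, lag.max = lag, plot = FALSE,
                  demean = TRUE)$acf[lag + 1])
}

#' Per-draw deviance for retained posterior samples
#'
#' Recomputes, for every retained draw, the deviance
#' `-2 * sum(trial log-likelihoods)` at that draw's subject-level
#' parameters.  This is the quantity whose posterior mean and variance
#' enter the deviance information criterion.
#'
#' @param chains a `ddm_chains` object from [sample_posterior()].
#' @param trials optional trial table; must contain the same participants
#'   the model was built from (used as a consistency check and data
#'   source; defaults to the data stored in the model).
#' @return Numeric vector of deviance values (chains concatenated).
#' @export
deviance_samples <- function(chains, trials = NULL) {
  stopifnot(inherits(chains, "ddm_chains"))
  model <- chains$model
  if (!is.null(trials)) {
    if (!setequal(unique(trials$participant_id), model$participant_ids))
      stop("trial table participants do not match the fitted model")
    model <- build_ddm_model(trials, variant = model$variant,
                             fix_boundary = model$fix_boundary,
                             gh_nodes = length(model$gh$x))
    model$data <- model$data[match(chains$participant_ids,
                                   model$participant_ids)]
  }
  P <- length(chains$participant_ids)
  kept <- dim(chains$draws)[1]
  dev <- numeric(kept * chains$n_chains)
  idx <- 0L
  for (k in seq_len(chains$n_chains)) {
    for (i in seq_len(kept)) {
      ll <- 0
      for (p in seq_len(P)) {
        th <- c(w_taste = chains$draws[i, k, sprintf("w_taste[%d]", p)],
                w_health = chains$draws[i, k, sprintf("w_health[%d]", p)],
                bias = chains$draws[i, k, sprintf("bias[%d]", p)],
                boundary = chains$draws[i, k, sprintf("boundary[%d]", p)],
                ndt = chains$draws[i, k, sprintf("ndt[%d]", p)],
                s2d = chains$draws[i, k, sprintf("s2d[%d]", p)])
        names(th) <- c("w_taste", "w_health", "bias", "boundary", "ndt",
                       "s2d")
        ll <- ll + subject_loglik(model, p, th, -1e10)
      }
      idx <- idx + 1L
      dev[idx] <- -2 * ll
    }
  }
  dev
}

#' Posterior means of a subject-level parameter family
#'
#' @param chains a `ddm_chains` object.
#' @param family one of `"w_taste"`, `"w_health"`, `"bias"`, `"boundary"`,
#'   `"ndt"`, `"s2d"`.
#' @return Named numeric vector, one posterior mean per participant.
#' @export
subject_posterior_means <- function(chains, family = "w_taste") {
  stopifnot(inherits(chains, "ddm_chains"))
  P <- length(chains$participant_ids)
  means <- vapply(seq_len(P), function(p)
    mean(chains$draws[, , sprintf("%s[%d]", family, p)]), numeric(1))
  stats::setNames(means, chains$participant_ids)
}

#' Concatenate the chains of one parameter into a single vector
#'
#' Post-burn-in, thinned draws from all chains, paired by draw index
#' (chain 1 first).
#'
#' @param chains a `ddm_chains` object.
#' @param parameter parameter name (e.g. `"mu_w_taste"`).
#' @return Numeric vector of length iterations x chains.
#' @export
concat_chains <- function(chains, parameter) {
  stopifnot(inherits(chains, "ddm_chains"),
            parameter %in% chains$parameters)
  as.vector(chains$draws[, , parameter])
}
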