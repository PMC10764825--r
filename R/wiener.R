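#' Wiener diffusion parameters
#'
#' Construct and validate the parameter set of a single-trial Wiener
#' diffusion process with absorbing boundaries at 0 ("no") and `boundary`
#' ("yes").  The within-trial noise standard deviation is fixed to 1, the
#' scaling convention in which all other parameters are expressed.
#'
#' @param boundary boundary separation (evidence units), > 0.
#' @param start_fraction starting point as a fraction of `boundary`, in
#'   (0, 1); 0.5 is unbiased, values above 0.5 favour "yes".
#' @param drift mean drift rate (evidence per second).
#' @param ndt non-decision time in seconds, >= 0.
#' @return A list of class `wiener_params`.
#' @export
wiener_params <- function(boundary, start_fraction, drift = 0, ndt = 0) {
  stopifnot(is.numeric(boundary), length(boundary) == 1L, boundary > 0,
            is.numeric(start_fraction), length(start_fraction) == 1L,
            start_fraction > 0, start_fraction < 1,
            is.numeric(drift), length(drift) == 1L, is.finite(drift),
            is.numeric(ndt), length(ndt) == 1L, ndt >= 0)
  structure(list(boundary = boundary, start_fraction = start_fraction,
                 drift = drift, ndt = ndt),
            class = "wiener_params")
}

#' Probability of absorption at the upper ("yes") boundary
#'
#' Closed-form absorption probability of the Wiener process:
#' \eqn{(1 - e^{-2 v a w}) / (1 - e^{-2 v a})} for drift \eqn{v \neq 0} and
#' \eqn{w} for \eqn{v = 0}, with boundary \eqn{a} and start fraction
#' \eqn{w}.
#'
#' @param params a [wiener_params()] object.
#' @return Probability in (0, 1).
#' @export
upper_probability <- function(params) {
  stopifnot(inherits(params, "wiener_params"))
  v <- params$drift
  a <- params$boundary
  w <- params$start_fraction
  if (abs(v * a) < 1e-9) return(w)
  expm1(-2 * v * a * w) / expm1(-2 * v * a)
}

#' Defective first-passage-time density
#'
#' Density (per second) of absorption at the named boundary at total
#' response time `t`, i.e. at decision time `t - ndt`.  The density is
#' defective: integrated over t it gives that boundary's absorption
#' probability, not 1.  Internally a small-time and a large-time series
#' expansion are used, switching at the point where each needs the fewer
#' terms for the target truncation error.
#'
#' @param t response times in seconds (vectorized); values at or below the
#'   non-decision time have density 0.
#' @param boundary_choice `"upper"`/`"yes"` or `"lower"`/`"no"`.
#' @param params a [wiener_params()] object.
#' @return Numeric vector of densities.
#' @export
fpt_density <- function(t, boundary_choice = c("upper", "lower", "yes", "no"),
                        params) {
  boundary_choice <- match.arg(boundary_choice)
  stopifnot(inherits(params, "wiener_params"), is.numeric(t))
  if (any(t < 0)) stop("negative response times are not allowed")
  upper <- boundary_choice %in% c("upper", "yes")
  dwiener_cpp(t, rep(upper, length(t)), params$boundary,
              params$start_fraction, params$drift, params$ndt)
}

#' Trial log-likelihood for a signed response time
#'
#' Log of the defective first-passage density at `|rt_signed|` for the
#' boundary implied by the sign of `rt_signed` (positive = "yes"/upper,
#' negative = "no"/lower).  Response times at or below the non-decision
#' time receive a large negative floor instead of `-Inf` so that MCMC
#' proposals fail gracefully.
#'
#' @param rt_signed signed response times in seconds; `|rt_signed| > 0`.
#' @param params a [wiener_params()] object.
#' @param floor_value log-density returned when the density is zero.
#' @return Numeric vector of log-densities.
#' @export
log_likelihood_trial <- function(rt_signed, params, floor_value = -1e10) {
  stopifnot(inherits(params, "wiener_params"), all(rt_signed != 0))
  dens <- dwiener_cpp(abs(rt_signed), rt_signed > 0, params$boundary,
                      params$start_fraction, params$drift, params$ndt)
  ifelse(dens > 0, log(dens), floor_value)
}

#' Mean drift rate from attribute ratings
#'
#' Linear attribute integration: the trial's mean drift is
#' `w_taste * taste + w_health * health`, with ratings on the 4-point code
#' \{-2, -1, 1, 2\} (0 is not a legal code).
#'
#' @param w_taste,w_health attribute weights on the drift rate.
#' @param taste,health rating codes in \{-2, -1, 1, 2\} (vectorized).
#' @return Numeric vector of drift rates (evidence per second).
#' @export
drift_mean <- function(w_taste, w_health, taste, health) {
  check_rating_codes(taste, "taste")
  check_rating_codes(health, "health")
  w_taste * taste + w_health * health
}

check_rating_codes <- function(x, what) {
  if (!all(x %in% c(-2, -1, 1, 2)))
    stop(sprintf("%s ratings must be coded -2, -1, 1 or 2 (got: %s)",
                 what, paste(unique(x[!x %in% c(-2, -1, 1, 2)]),
                             collapse = ", ")), call. = FALSE)
  invisible(x)
}

#' Simulate single Wiener trials by Euler-Maruyama
#'
#' Simulates the evidence path from `start_fraction * boundary` with
#' per-step increment `drift * dt + sqrt(dt) * N(0, 1)` until a boundary is
#' crossed.  The response time is the crossing time plus the non-decision
#' time; its sign codes the choice ("yes" positive).  Trials that do not
#' reach a boundary within `max_time` seconds of decision time are flagged
#' as censored and get `NA` response times.
#'
#' @param params a [wiener_params()] object; `params$drift` is recycled.
#' @param n number of trials (ignored if `drift_values` given).
#' @param drift_values optional vector of per-trial drift rates overriding
#'   `params$drift` (used for inter-trial drift variability).
#' @param dt Euler step in seconds (default 0.008, i.e. 8 ms).
#' @param max_time censoring horizon for the decision time, seconds.
#' @param seed optional integer seed.
#' @return data.frame with columns `choice` ("yes"/"no"), `rt_signed`, and
#'   logical `censored`.
#' @export
simulate_trial <- function(params, n = 1, drift_values = NULL, dt = 0.008,
                           max_time = 10, seed = NULL) {
  stopifnot(inherits(params, "wiener_params"), dt > 0, max_time > 0)
  if (!is.null(seed)) set.seed(seed)
  v <- if (is.null(drift_values)) rep(params$drift, n) else drift_values
  m <- simulate_wiener_cpp(v, params$boundary, params$start_fraction,
                           params$ndt, dt, max_time)
  data.frame(
    choice = ifelse(is.na(m[, 1]), NA_character_,
                    ifelse(m[, 1] > 0, "yes", "no")),
    rt_signed = m[, 1],
    censored = m[, 2] > 0,
    stringsAsFactors = FALSE
  )
}

# Gauss-Hermite nodes/weights for marginalizing the Wiener density over
# N(mean drift, s2) inter-trial drift variability.
gauss_hermite_rule <- function(n = 9) {
  gh <- pracma::gaussHermite(n)
  list(x = gh$x, w = gh$w)
}
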