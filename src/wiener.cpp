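#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time density at the LOWER boundary of a unit-boundary,
// zero-drift Wiener process started at fraction w, evaluated at normalized
// time tq = t / a^2.  Two series representations (small-time / large-time)
// with the truncation of each chosen for absolute error <= eps, and the
// cheaper representation used.
static double wfpt_core(const double tq, const double w, const double eps) {
  if (tq <= 0.0) return 0.0;

  // number of terms needed by each representation
  double ks = 2.0, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tq) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tq *
                         std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tq)));
    ks = std::max(ks, std::sqrt(tq) + 1.0);
  }
  if (M_PI * tq * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tq * eps) / (M_PI * M_PI * tq));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tq)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tq));
  }

  double p = 0.0;
  if (ks < kl) {            // small-time expansion
    const int K = (int)std::ceil(ks);
    const int lo = -((K - 1) / 2), hi = (K - 1) / 2 + ((K - 1) % 2);
    for (int k = lo; k <= hi; ++k) {
      const double z = w + 2.0 * k;
      p += z * std::exp(-z * z / (2.0 * tq));
    }
    p /= std::sqrt(2.0 * M_PI * tq * tq * tq);
  } else {                  // large-time expansion
    const int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * tq / 2.0) *
           std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p > 0.0 ? p : 0.0;
}

// Defective density of absorption at one boundary at total time t
// (decision time t - tau), for boundary separation a, start fraction w
// (from the lower boundary), drift v, non-decision time tau, noise s = 1.
// upper = true gives the "yes" (upper) boundary via reflection.
static double dwiener_one(const double t, const bool upper, const double a,
                          const double w, const double v, const double tau) {
  const double u = t - tau;
  if (u <= 0.0 || a <= 0.0 || w <= 0.0 || w >= 1.0) return 0.0;
  const double ww = upper ? 1.0 - w : w;
  const double vv = upper ? -v : v;
  const double tq = u / (a * a);
  return std::exp(-vv * a * ww - vv * vv * u / 2.0) / (a * a) *
         wfpt_core(tq, ww, 1e-10);
}

// [[Rcpp::export]]
NumericVector dwiener_cpp(NumericVector t, LogicalVector upper, double a,
                          double w, double v, double tau) {
  const R_xlen_t n = t.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = dwiener_one(t[i], upper[i % upper.size()], a, w, v, tau);
  return out;
}

// Per-trial log densities for one subject under the two-attribute DDM with
// inter-trial drift variability: the Wiener density is marginalized over
// delta ~ N(w_taste*TD + w_health*HD, s2d) with Gauss-Hermite nodes ghx and
// weights ghw (for integral against exp(-x^2)).  rt_signed > 0 codes "yes"
// (upper boundary).  Densities <= 0 or |rt| <= tau get the floor value so
// MCMC proposals fail gracefully instead of returning -Inf.
// [[Rcpp::export]]
NumericVector ddm_loglik_trials(NumericVector rt_signed, NumericVector td,
                                NumericVector hd, double w_taste,
                                double w_health, double bias, double bound,
                                double ndt, double s2d, NumericVector ghx,
                                NumericVector ghw,
                                double floor_val = -1e10) {
  const R_xlen_t n = rt_signed.size();
  const R_xlen_t K = ghx.size();
  const double sq = std::sqrt(2.0 * s2d);
  const double inv_sqrt_pi = 1.0 / std::sqrt(M_PI);
  NumericVector out(n);
  const bool ok = bound > 0.0 && bias > 0.0 && bias < 1.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double t = std::fabs(rt_signed[i]);
    const bool upper = rt_signed[i] > 0.0;
    const double m = w_taste * td[i] + w_health * hd[i];
    double dens = 0.0;
    const double u = t - ndt;
    if (u > 0.0 && ok) {
      // the drift-free part of the density is shared by all GH nodes
      const double ww = upper ? 1.0 - bias : bias;
      const double core =
        wfpt_core(u / (bound * bound), ww, 1e-10) / (bound * bound);
      if (core > 0.0) {
        if (s2d < 1e-12) {
          const double vv = upper ? -m : m;
          dens = std::exp(-vv * bound * ww - vv * vv * u / 2.0) * core;
        } else {
          for (R_xlen_t k = 0; k < K; ++k) {
            const double v = m + sq * ghx[k];
            const double vv = upper ? -v : v;
            dens += ghw[k] *
              std::exp(-vv * bound * ww - vv * vv * u / 2.0);
          }
          dens *= core * inv_sqrt_pi;
        }
      }
    }
    out[i] = (dens > 0.0) ? std::log(dens) : floor_val;
  }
  return out;
}

// [[Rcpp::export]]
double ddm_loglik_sum(NumericVector rt_signed, NumericVector td,
                      NumericVector hd, double w_taste, double w_health,
                      double bias, double bound, double ndt, double s2d,
                      NumericVector ghx, NumericVector ghw,
                      double floor_val = -1e10) {
  NumericVector ll = ddm_loglik_trials(rt_signed, td, hd, w_taste, w_health,
                                       bias, bound, ndt, s2d, ghx, ghw,
                                       floor_val);
  double s = 0.0;
  for (R_xlen_t i = 0; i < ll.size(); ++i) s += ll[i];
  return s;
}

// Euler-Maruyama walk between absorbing boundaries 0 and a, start w*a,
// per-trial drift v[i], step dt: increment v*dt + sqrt(dt)*N(0,1).
// Returns a matrix with columns (rt_signed, censored); censored trials get
// rt_signed = NA.  Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
NumericMatrix simulate_wiener_cpp(NumericVector v, double a, double w,
                                  double tau, double dt, double max_t) {
  const R_xlen_t n = v.size();
  NumericMatrix out(n, 2);
  const double sdt = std::sqrt(dt);
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = w * a, t = 0.0;
    int choice = -1;                      // -1 = undecided
    while (t < max_t) {
      x += v[i] * dt + sdt * norm_rand();
      t += dt;
      if (x >= a) { choice = 1; break; }
      if (x <= 0.0) { choice = 0; break; }
    }
    if (choice < 0) {
      out(i, 0) = NA_REAL;
      out(i, 1) = 1.0;
    } else {
      out(i, 0) = (choice == 1) ? (tau + t) : -(tau + t);
      out(i, 1) = 0.0;
    }
  }
  return out;
}
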