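#include <Rcpp.h>
using namespace Rcpp;

// Augmented-data Tweedie machinery. The compound Poisson density is handled
// entirely through the joint density of (Y, U): the intractable normalizing
// constant of the marginal never appears. All functions are deterministic
// given their inputs; any randomness is supplied by the caller as uniforms
// drawn from R's RNG so that chains are reproducible under set.seed().

static inline double logw_term(double u, double c1, double alpha) {
  // log weight of the latent-count series at u >= 1 for a fixed y > 0:
  //   w_u = lambda^u (y/gamma)^{u alpha} / (u! Gamma(u alpha))
  return u * c1 - R::lgammafn(u + 1.0) - R::lgammafn(u * alpha);
}

// Locate the (unique) mode of the log-concave series.
static int series_mode(double c1, double alpha, int cap) {
  int a = 1;
  while (a < cap && logw_term(2.0 * a, c1, alpha) > logw_term((double)a, c1, alpha))
    a *= 2;
  int lo = a / 2 < 1 ? 1 : a / 2;
  int hi = 2 * a < cap ? 2 * a : cap;
  while (lo < hi) {
    int mid = lo + (hi - lo) / 2;
    if (logw_term(mid + 1.0, c1, alpha) > logw_term((double)mid, c1, alpha))
      lo = mid + 1;
    else
      hi = mid;
  }
  return lo;
}

// Enumerate the series around its mode until terms fall `drop` nats below the
// maximum; fills `w` with weights on exp scale relative to the mode and
// returns the first index. Sets *converged = false when the cap bites.
static int enumerate_series(double c1, double alpha, int cap, double drop,
                            std::vector<double>& w, double& lmax,
                            bool& converged) {
  int mode = series_mode(c1, alpha, cap);
  lmax = logw_term((double)mode, c1, alpha);
  int lo = mode;
  while (lo > 1 && logw_term(lo - 1.0, c1, alpha) > lmax - drop) --lo;
  int hi = mode;
  converged = true;
  while (hi < cap && logw_term(hi + 1.0, c1, alpha) > lmax - drop) ++hi;
  if (hi == cap && logw_term((double)cap, c1, alpha) > lmax - drop)
    converged = false;
  w.resize(hi - lo + 1);
  for (int u = lo; u <= hi; ++u)
    w[u - lo] = std::exp(logw_term((double)u, c1, alpha) - lmax);
  return lo;
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_tw_joint_loglik(NumericVector y, IntegerVector u,
                                  NumericVector lambda, double alpha,
                                  NumericVector gamma) {
  int n = y.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double yi = y[i];
    int ui = u[i];
    if (yi <= 0.0) {
      out[i] = (ui == 0) ? -lambda[i] : R_NegInf;
    } else if (ui < 1) {
      out[i] = R_NegInf;
    } else {
      double ua = ui * alpha;
      out[i] = (ua - 1.0) * std::log(yi) - yi / gamma[i] - R::lgammafn(ua) -
               ua * std::log(gamma[i]) + ui * std::log(lambda[i]) -
               R::lgammafn(ui + 1.0) - lambda[i];
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_draw_u(NumericVector y, NumericVector lambda, double alpha,
                         NumericVector gamma, NumericVector unif,
                         int max_terms) {
  int n = y.size();
  IntegerVector out(n);
  std::vector<double> w;
  int warned = 0;
  for (int i = 0; i < n; ++i) {
    if (y[i] <= 0.0) {
      out[i] = 0;
      continue;
    }
    double c1 = std::log(lambda[i]) + alpha * std::log(y[i] / gamma[i]);
    double lmax;
    bool conv;
    int lo = enumerate_series(c1, alpha, max_terms, 40.0, w, lmax, conv);
    if (!conv && !warned) {
      Rcpp::warning("latent-count series hit the truncation cap; tail mass may be non-negligible");
      warned = 1;
    }
    double tot = 0.0;
    for (size_t k = 0; k < w.size(); ++k) tot += w[k];
    double target = unif[i] * tot, acc = 0.0;
    int pick = lo + (int)w.size() - 1;
    for (size_t k = 0; k < w.size(); ++k) {
      acc += w[k];
      if (acc >= target) {
        pick = lo + (int)k;
        break;
      }
    }
    out[i] = pick;
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_u_logsum(NumericVector y, NumericVector lambda, double alpha,
                           NumericVector gamma, int max_terms) {
  // log sum_{u>=1} w_u for each positive y (the series part of the marginal
  // density); -Inf for y <= 0 where the series is empty.
  int n = y.size();
  NumericVector out(n);
  std::vector<double> w;
  int warned = 0;
  for (int i = 0; i < n; ++i) {
    if (y[i] <= 0.0) {
      out[i] = R_NegInf;
      continue;
    }
    double c1 = std::log(lambda[i]) + alpha * std::log(y[i] / gamma[i]);
    double lmax;
    bool conv;
    enumerate_series(c1, alpha, max_terms, 37.0, w, lmax, conv);
    if (!conv && !warned) {
      Rcpp::warning("marginal density series not converged at the term cap");
      warned = 1;
    }
    double tot = 0.0;
    for (size_t k = 0; k < w.size(); ++k) tot += w[k];
    out[i] = lmax + std::log(tot);
  }
  return out;
}
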