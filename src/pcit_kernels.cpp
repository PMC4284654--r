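#include <Rcpp.h>
using namespace Rcpp;

// Evaluate three-segment piecewise-linear curves at a set of points.
// curves: n_curves x 6 (x1, x2, y0, y1, y2, y3) with implicit x0 = -1,
// x3 = 1. Returns length(x) x n_curves.
// [[Rcpp::export]]
NumericMatrix cpp_eval_curves(NumericMatrix curves, NumericVector x) {
  const int nc = curves.nrow(), nx = x.size();
  NumericMatrix out(nx, nc);
  for (int c = 0; c < nc; ++c) {
    double kx[4] = {-1.0, curves(c, 0), curves(c, 1), 1.0};
    double ky[4] = {curves(c, 2), curves(c, 3), curves(c, 4), curves(c, 5)};
    for (int i = 0; i < nx; ++i) {
      const double xi = x[i];
      double y;
      if (xi <= kx[0]) {
        y = ky[0];
      } else if (xi >= kx[3]) {
        y = ky[3];
      } else {
        int s = 0;
        while (s < 2 && xi > kx[s + 1]) ++s;
        // collapsed segment (kx[s] == kx[s+1]) cannot contain xi strictly;
        // take the left height if it does numerically
        const double w = kx[s + 1] - kx[s];
        y = (w > 0.0) ? ky[s] + (ky[s + 1] - ky[s]) * (xi - kx[s]) / w
                      : ky[s];
      }
      out(i, c) = y;
    }
  }
  return out;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Profile the intercept beta0 per curve by Newton ascent on the concave
// fractional-Bernoulli log-likelihood sum_i y_i log p_i + (1-y_i) log(1-p_i)
// with p_i = plogis(beta0 + delta_ic). delta: n_items x n_curves.
// Returns beta0 and the maximized log-likelihood per curve.
// [[Rcpp::export]]
List cpp_profile_beta0(NumericMatrix delta, NumericVector y,
                       double lower, double upper, double tol,
                       int max_iter) {
  const int n = delta.nrow(), nc = delta.ncol();
  NumericVector beta0(nc), loglik(nc);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  const double eps = 1e-12;
  ybar = clampd(ybar, eps, 1.0 - eps);
  const double b_init = clampd(std::log(ybar / (1.0 - ybar)), lower, upper);
  for (int c = 0; c < nc; ++c) {
    const double* d = &delta(0, c);
    double b = b_init;
    for (int it = 0; it < max_iter; ++it) {
      double g = 0.0, h = 0.0;
      for (int i = 0; i < n; ++i) {
        const double p = 1.0 / (1.0 + std::exp(-(b + d[i])));
        g += y[i] - p;
        h += p * (1.0 - p);
      }
      if (h < 1e-10) h = 1e-10;
      const double step = g / h;
      const double b_new = clampd(b + step, lower, upper);
      const bool at_bound = (b_new <= lower && g < 0) ||
                            (b_new >= upper && g > 0);
      const double moved = std::fabs(b_new - b);
      b = b_new;
      if (std::fabs(step) < tol || at_bound || moved < tol) break;
    }
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-(b + d[i])));
      p = clampd(p, eps, 1.0 - eps);
      ll += y[i] * std::log(p) + (1.0 - y[i]) * std::log(1.0 - p);
    }
    beta0[c] = b;
    loglik[c] = ll;
  }
  return List::create(_["beta0"] = beta0, _["loglik"] = loglik);
}
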