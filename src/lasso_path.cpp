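#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double soft(double z, double l) {
  if (z > l) return z - l;
  if (z < -l) return z + l;
  return 0.0;
}

// Coordinate-descent lasso down a geometric lambda path, recording the
// first `q` predictors to enter the active set. Columns of X and each
// response are centered (and X scaled to unit variance) internally, so
// the caller can pass raw subsample rows. Only the order of entry is
// needed, so convergence at each lambda uses an active-set sweep with a
// moderate tolerance. Returns a p x L 0/1 matrix marking, for each
// response column of Y, the first q predictors on the path.
// [[Rcpp::export]]
IntegerMatrix lasso_first_q(NumericMatrix X, NumericMatrix Y, int q,
                            int nlambda = 40, double lambda_min_ratio = 0.02,
                            int max_iter = 200, double tol = 1e-4) {
  const int n = X.nrow(), p = X.ncol(), L = Y.ncol();
  if (q < 1) stop("q must be >= 1");
  if (Y.nrow() != n) stop("X and Y row counts differ");

  // standardized copy of X (column-major, unit variance, mean zero)
  std::vector<double> Xs((size_t)n * p);
  std::vector<bool> degenerate(p, false);
  for (int j = 0; j < p; ++j) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += X(i, j);
    m /= n;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      double c = X(i, j) - m;
      Xs[(size_t)j * n + i] = c;
      ss += c * c;
    }
    double s = std::sqrt(ss / n);
    if (s < 1e-12) {
      degenerate[j] = true;
      for (int i = 0; i < n; ++i) Xs[(size_t)j * n + i] = 0.0;
    } else {
      for (int i = 0; i < n; ++i) Xs[(size_t)j * n + i] /= s;
    }
  }

  IntegerMatrix out(p, L);
  std::vector<double> r(n), beta(p);
  std::vector<int> order, active;
  std::vector<bool> entered(p), in_active(p);

  for (int l = 0; l < L; ++l) {
    double ym = 0.0;
    for (int i = 0; i < n; ++i) ym += Y(i, l);
    ym /= n;
    double lam_max = 0.0;
    for (int i = 0; i < n; ++i) r[i] = Y(i, l) - ym;
    for (int j = 0; j < p; ++j) {
      if (degenerate[j]) continue;
      double c = 0.0;
      const double *xj = &Xs[(size_t)j * n];
      for (int i = 0; i < n; ++i) c += xj[i] * r[i];
      c = std::fabs(c) / n;
      if (c > lam_max) lam_max = c;
    }
    std::fill(beta.begin(), beta.end(), 0.0);
    std::fill(entered.begin(), entered.end(), false);
    std::fill(in_active.begin(), in_active.end(), false);
    order.clear();
    active.clear();
    if (lam_max <= 0.0) continue;  // constant response

    const double ratio = std::pow(lambda_min_ratio, 1.0 / (nlambda - 1));
    double lam = lam_max;
    bool done = false;

    // one coordinate update; returns the absolute change
    auto update = [&](int j, double lambda) -> double {
      const double *xj = &Xs[(size_t)j * n];
      double rho = 0.0;
      for (int i = 0; i < n; ++i) rho += xj[i] * r[i];
      double z = beta[j] + rho / n;
      double bnew = soft(z, lambda);
      double d = bnew - beta[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
        beta[j] = bnew;
        if (bnew != 0.0 && !entered[j]) {
          entered[j] = true;
          order.push_back(j);
        }
        if (bnew != 0.0 && !in_active[j]) {
          in_active[j] = true;
          active.push_back(j);
        }
      }
      return std::fabs(d);
    };

    for (int k = 1; k < nlambda && !done; ++k) {
      lam *= ratio;
      for (int it = 0; it < max_iter; ++it) {
        // full sweep: may recruit new coordinates
        double max_delta = 0.0;
        for (int j = 0; j < p; ++j) {
          if (degenerate[j]) continue;
          double d = update(j, lam);
          if ((int)order.size() >= q) { done = true; break; }
          if (d > max_delta) max_delta = d;
        }
        if (done || max_delta < tol) break;
        // inner active-set sweeps until stable
        for (int it2 = 0; it2 < max_iter; ++it2) {
          double md = 0.0;
          for (size_t a = 0; a < active.size(); ++a) {
            double d = update(active[a], lam);
            if ((int)order.size() >= q) { done = true; break; }
            if (d > md) md = d;
          }
          if (done || md < tol) break;
        }
        if (done) break;
      }
    }
    int keep = std::min<int>(q, order.size());
    for (int k = 0; k < keep; ++k) out(order[k], l) = 1;
  }
  return out;
}
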