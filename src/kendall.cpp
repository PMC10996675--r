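#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Kendall tau-b between two feature profiles, pairwise-complete.
// tau_b = (C - D) / sqrt((n0 - n1) (n0 - n2)),
//   n0 = n (n - 1) / 2, n1/n2 = sum t_i (t_i - 1) / 2 over tie groups of x/y.
// Returns NA when fewer than 2 complete pairs remain or either profile is
// constant over the complete pairs (denominator 0).
static double tau_b_pair(const double* x, const double* y, int n,
                         std::vector<double>& xs, std::vector<double>& ys,
                         int& n_used) {
  xs.clear();
  ys.clear();
  for (int i = 0; i < n; ++i) {
    if (!ISNAN(x[i]) && !ISNAN(y[i])) {
      xs.push_back(x[i]);
      ys.push_back(y[i]);
    }
  }
  const int m = (int) xs.size();
  n_used = m;
  if (m < 2) return NA_REAL;

  double conc_minus_disc = 0.0, ties_x = 0.0, ties_y = 0.0;
  for (int i = 0; i < m - 1; ++i) {
    for (int j = i + 1; j < m; ++j) {
      const double dx = xs[i] - xs[j];
      const double dy = ys[i] - ys[j];
      if (dx == 0.0 && dy == 0.0) {
        ties_x += 1.0;
        ties_y += 1.0;
      } else if (dx == 0.0) {
        ties_x += 1.0;
      } else if (dy == 0.0) {
        ties_y += 1.0;
      } else if ((dx > 0.0) == (dy > 0.0)) {
        conc_minus_disc += 1.0;
      } else {
        conc_minus_disc -= 1.0;
      }
    }
  }
  const double n0 = 0.5 * (double) m * (double) (m - 1);
  const double den_x = n0 - ties_x;
  const double den_y = n0 - ties_y;
  if (den_x <= 0.0 || den_y <= 0.0) return NA_REAL;  // constant vector
  return conc_minus_disc / std::sqrt(den_x * den_y);
}

// [[Rcpp::export(name = ".cross_kendall_cpp")]]
List cross_kendall_cpp(NumericMatrix X, NumericMatrix Y) {
  // X, Y: samples in rows (shared), features in columns.
  const int n = X.nrow();
  if (Y.nrow() != n) stop("X and Y must have the same number of rows");
  const int p = X.ncol(), q = Y.ncol();
  NumericMatrix tau(p, q);
  IntegerMatrix npairs(p, q);
  std::vector<double> xs, ys;
  xs.reserve(n);
  ys.reserve(n);
  for (int i = 0; i < p; ++i) {
    const double* xcol = &X(0, i);
    for (int j = 0; j < q; ++j) {
      int m = 0;
      tau(i, j) = tau_b_pair(xcol, &Y(0, j), n, xs, ys, m);
      npairs(i, j) = m;
    }
  }
  return List::create(_["tau"] = tau, _["n_pairs"] = npairs);
}

// [[Rcpp::export(name = ".kendall_tau_b_cpp")]]
List kendall_tau_b_cpp(NumericVector x, NumericVector y) {
  if (x.size() != y.size()) stop("x and y must have the same length");
  std::vector<double> xs, ys;
  int m = 0;
  double t = tau_b_pair(x.begin(), y.begin(), (int) x.size(), xs, ys, m);
  return List::create(_["tau"] = t, _["n"] = m);
}
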