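#include <Rcpp.h>
using namespace Rcpp;

// Pentadiagonal SPD solve via banded LDL^T (half-bandwidth 2), O(n).
// a0: diagonal (n), a1: first superdiagonal (n-1), a2: second (n-2).
static void band_ldl_solve(const std::vector<double>& a0,
                           const std::vector<double>& a1,
                           const std::vector<double>& a2,
                           const std::vector<double>& b,
                           std::vector<double>& x) {
  const int n = (int)a0.size();
  std::vector<double> d(n), l1(n, 0.0), l2(n, 0.0); // l1[i]=L[i][i-1], l2[i]=L[i][i-2]
  for (int i = 0; i < n; ++i) {
    double li2 = 0.0, li1 = 0.0;
    if (i >= 2) li2 = a2[i - 2] / d[i - 2];
    if (i >= 1) {
      double s = a1[i - 1];
      if (i >= 2) s -= li2 * l1[i - 1] * d[i - 2];
      li1 = s / d[i - 1];
    }
    double di = a0[i];
    if (i >= 1) di -= li1 * li1 * d[i - 1];
    if (i >= 2) di -= li2 * li2 * d[i - 2];
    l1[i] = li1; l2[i] = li2; d[i] = di;
  }
  // forward: L z = b
  x.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = b[i];
    if (i >= 1) s -= l1[i] * x[i - 1];
    if (i >= 2) s -= l2[i] * x[i - 2];
    x[i] = s;
  }
  for (int i = 0; i < n; ++i) x[i] /= d[i];
  // backward: L^T y = z
  for (int i = n - 1; i >= 0; --i) {
    double s = x[i];
    if (i + 1 < n) s -= l1[i + 1] * x[i + 1];
    if (i + 2 < n) s -= l2[i + 2] * x[i + 2];
    x[i] = s;
  }
}

// Asymmetric least squares baseline (Eilers & Boelens): minimize
// sum_i w_i (y_i - z_i)^2 + lambda * sum (Delta^2 z)^2 with
// w_i = p for y_i > z_i, 1 - p otherwise, iterated.
// [[Rcpp::export(name = ".als_baseline_cpp")]]
NumericVector als_baseline_cpp(NumericVector y, double lambda, double p,
                               int iterations) {
  const int n = y.size();
  if (n < 3) stop("ALS baseline needs at least 3 samples");
  // D'D for second differences: diag, first and second superdiagonals
  std::vector<double> dd0(n, 0.0), dd1(n - 1, 0.0), dd2(n - 2, 0.0);
  for (int k = 0; k <= n - 3; ++k) { // row k of D has (1, -2, 1) at k, k+1, k+2
    dd0[k] += 1.0; dd0[k + 1] += 4.0; dd0[k + 2] += 1.0;
    dd1[k] += -2.0; dd1[k + 1] += -2.0;
    dd2[k] += 1.0;
  }
  std::vector<double> w(n, 1.0), a0(n), a1(n - 1), a2(n - 2), rhs(n), z(n, 0.0);
  for (int i = 0; i < n - 1; ++i) a1[i] = lambda * dd1[i];
  for (int i = 0; i < n - 2; ++i) a2[i] = lambda * dd2[i];
  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < n; ++i) {
      a0[i] = w[i] + lambda * dd0[i];
      rhs[i] = w[i] * y[i];
    }
    band_ldl_solve(a0, a1, a2, rhs, z);
    for (int i = 0; i < n; ++i) w[i] = (y[i] > z[i]) ? p : (1.0 - p);
  }
  return NumericVector(z.begin(), z.end());
}
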