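#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// digamma at integer arguments 1..n via psi(m+1) = psi(m) + 1/m
static std::vector<double> psi_table(int n) {
  std::vector<double> psi(n + 1);
  psi[1] = R::digamma(1.0);
  for (int m = 1; m < n; ++m) psi[m + 1] = psi[m] + 1.0 / m;
  return psi;
}

// Kraskov-Stoegbauer-Grassberger estimator (algorithm 1) for one pair:
// I(X;Y) = psi(k) + psi(n) - < psi(nx+1) + psi(ny+1) >
// with eps_i the max-norm distance to the k-th neighbour and nx, ny the
// counts of marginal neighbours strictly inside eps_i. O(n^2) per pair.
static double ksg_pair(const double* x, const double* y, int n, int k,
                       const std::vector<double>& psi,
                       std::vector<double>& d) {
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = std::fabs(x[i] - x[j]);
      double dy = std::fabs(y[i] - y[j]);
      d[m++] = dx > dy ? dx : dy;
    }
    std::nth_element(d.begin(), d.begin() + (k - 1), d.begin() + m);
    double eps = d[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (std::fabs(x[i] - x[j]) < eps) ++nx;
      if (std::fabs(y[i] - y[j]) < eps) ++ny;
    }
    acc += psi[nx + 1] + psi[ny + 1];
  }
  return psi[k] + psi[n] - acc / n;
}

// [[Rcpp::export]]
double ksg_mi_cpp(NumericVector x, NumericVector y, int k) {
  int n = x.size();
  std::vector<double> psi = psi_table(n + 1);
  std::vector<double> d(n - 1);
  return ksg_pair(x.begin(), y.begin(), n, k, psi, d);
}

// X: n samples x p features, Y: n samples x q features -> p x q MI matrix
// [[Rcpp::export]]
NumericMatrix mi_matrix_cpp(NumericMatrix X, NumericMatrix Y, int k) {
  int n = X.nrow(), p = X.ncol(), q = Y.ncol();
  std::vector<double> psi = psi_table(n + 1);
  std::vector<double> d(n - 1);
  NumericMatrix out(p, q);
  for (int a = 0; a < p; ++a) {
    const double* xa = &X(0, a);
    for (int b = 0; b < q; ++b) {
      out(a, b) = ksg_pair(xa, &Y(0, b), n, k, psi, d);
      if (b % 256 == 0) Rcpp::checkUserInterrupt();
    }
  }
  return out;
}
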