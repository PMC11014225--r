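#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Asymmetric least squares baseline (Whittaker smoother with asymmetric
// weights). Solves (W + lambda * D2' D2) z = W y repeatedly, updating
// w_i = p if y_i > z_i else 1 - p. The system matrix is pentadiagonal;
// solved with a banded Cholesky factorisation, O(n) per iteration.
// [[Rcpp::export(name = ".als_baseline_cpp")]]
List als_baseline_cpp(NumericVector y, double lambda, double p, int maxit) {
  const int n = y.size();
  if (n < 5) stop("trace too short for baseline estimation");

  // penalty bands of lambda * D2' D2 (D2 = second-difference operator)
  std::vector<double> p0(n, 0.0), p1(n - 1, 0.0), p2(n - 2, 0.0);
  const double c[3] = {1.0, -2.0, 1.0};
  for (int j = 0; j < n - 2; ++j) {
    for (int a = 0; a < 3; ++a) {
      p0[j + a] += lambda * c[a] * c[a];
      if (a < 2) p1[j + a] += lambda * c[a] * c[a + 1];
      if (a < 1) p2[j + a] += lambda * c[a] * c[a + 2];
    }
  }

  std::vector<double> w(n, 1.0), wprev(n), z(n, 0.0);
  std::vector<double> d0(n), d1(n - 1), d2(n - 2), rhs(n);
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < maxit; ++iter) {
    // assemble bands: diag = w + penalty
    for (int i = 0; i < n; ++i) d0[i] = w[i] + p0[i];
    for (int i = 0; i < n - 1; ++i) d1[i] = p1[i];
    for (int i = 0; i < n - 2; ++i) d2[i] = p2[i];
    for (int i = 0; i < n; ++i) rhs[i] = w[i] * y[i];

    // banded Cholesky: M = L D L' with bandwidth 2
    // store L subdiagonals in d1 (first) and d2 (second), D in d0
    for (int i = 0; i < n; ++i) {
      double di = d0[i];
      if (i >= 1) di -= d1[i - 1] * d1[i - 1] * d0[i - 1];
      if (i >= 2) di -= d2[i - 2] * d2[i - 2] * d0[i - 2];
      if (di <= 0.0) stop("baseline system not positive definite");
      d0[i] = di;
      if (i + 1 < n) {
        double e = d1[i];
        if (i >= 1) e -= d2[i - 1] * d1[i - 1] * d0[i - 1];
        d1[i] = e / di;
      }
      if (i + 2 < n) d2[i] = d2[i] / di;
    }
    // forward solve L v = rhs
    for (int i = 0; i < n; ++i) {
      double v = rhs[i];
      if (i >= 1) v -= d1[i - 1] * rhs[i - 1];
      if (i >= 2) v -= d2[i - 2] * rhs[i - 2];
      rhs[i] = v;
    }
    // diagonal + back solve L' z = D^{-1} v
    for (int i = n - 1; i >= 0; --i) {
      double v = rhs[i] / d0[i];
      if (i + 1 < n) v -= d1[i] * z[i + 1];
      if (i + 2 < n) v -= d2[i] * z[i + 2];
      z[i] = v;
    }

    wprev = w;
    for (int i = 0; i < n; ++i) w[i] = (y[i] > z[i]) ? p : (1.0 - p);
    bool same = true;
    for (int i = 0; i < n; ++i) {
      if (w[i] != wprev[i]) { same = false; break; }
    }
    if (same) { converged = true; break; }
  }

  return List::create(_["baseline"] = NumericVector(z.begin(), z.end()),
                      _["converged"] = converged,
                      _["iterations"] = iter + 1);
}

// single weighted Whittaker smooth: solves (W + lambda D2'D2) z = W y
// for externally supplied non-negative weights (used to bridge the
// baseline across masked peak regions)
// [[Rcpp::export(name = ".whittaker_cpp")]]
NumericVector whittaker_cpp(NumericVector y, NumericVector w, double lambda) {
  const int n = y.size();
  if (w.size() != n) stop("weights length mismatch");
  std::vector<double> p0(n, 0.0), p1(n - 1, 0.0), p2(n - 2, 0.0);
  const double c[3] = {1.0, -2.0, 1.0};
  for (int j = 0; j < n - 2; ++j)
    for (int a = 0; a < 3; ++a) {
      p0[j + a] += lambda * c[a] * c[a];
      if (a < 2) p1[j + a] += lambda * c[a] * c[a + 1];
      if (a < 1) p2[j + a] += lambda * c[a] * c[a + 2];
    }
  std::vector<double> d0(n), d1(n - 1), d2(n - 2), rhs(n), z(n);
  for (int i = 0; i < n; ++i) d0[i] = w[i] + p0[i];
  for (int i = 0; i < n - 1; ++i) d1[i] = p1[i];
  for (int i = 0; i < n - 2; ++i) d2[i] = p2[i];
  for (int i = 0; i < n; ++i) rhs[i] = w[i] * y[i];
  for (int i = 0; i < n; ++i) {
    double di = d0[i];
    if (i >= 1) di -= d1[i - 1] * d1[i - 1] * d0[i - 1];
    if (i >= 2) di -= d2[i - 2] * d2[i - 2] * d0[i - 2];
    if (di <= 0.0) stop("smoother system not positive definite");
    d0[i] = di;
    if (i + 1 < n) {
      double e = d1[i];
      if (i >= 1) e -= d2[i - 1] * d1[i - 1] * d0[i - 1];
      d1[i] = e / di;
    }
    if (i + 2 < n) d2[i] = d2[i] / di;
  }
  for (int i = 0; i < n; ++i) {
    double v = rhs[i];
    if (i >= 1) v -= d1[i - 1] * rhs[i - 1];
    if (i >= 2) v -= d2[i - 2] * rhs[i - 2];
    rhs[i] = v;
  }
  for (int i = n - 1; i >= 0; --i) {
    double v = rhs[i] / d0[i];
    if (i + 1 < n) v -= d1[i] * z[i + 1];
    if (i + 2 < n) v -= d2[i] * z[i + 2];
    z[i] = v;
  }
  return NumericVector(z.begin(), z.end());
}
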