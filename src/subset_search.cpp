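#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shrunken pooled within-class covariance LDA, scored by leave-one-out
// cross-validation, evaluated over many column subsets of X at once.
//
// For each subset: S = pooled within-class covariance (denominator
// n_fit - 2), S_lam = (1 - lam) S + lam (tr(S)/k) I, w = S_lam^{-1}
// (mu1 - mu0), threshold = w.(mu1 + mu0)/2, predict positive iff
// score >= threshold. LOOCV uses rank-one downdates of the class sums
// and outer-product accumulators, so each fold costs O(k^2) + O(k^3)
// for the small solve.
//
// X: n x p, y: integer 0/1 (1 = positive class), subsets: k x m matrix
// of 0-based column indices. Returns accuracy and training-set Fisher
// separation J = (mu1-mu0)' S_lam^{-1} (mu1-mu0) per subset.

static bool solve_spd(std::vector<double> &A, std::vector<double> &b, int k) {
  // Gaussian elimination with partial pivoting on k x k (row-major)
  for (int c = 0; c < k; ++c) {
    int piv = c;
    double best = std::fabs(A[c * k + c]);
    for (int r = c + 1; r < k; ++r) {
      double v = std::fabs(A[r * k + c]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-300) return false;
    if (piv != c) {
      for (int j = 0; j < k; ++j) std::swap(A[c * k + j], A[piv * k + j]);
      std::swap(b[c], b[piv]);
    }
    double d = A[c * k + c];
    for (int r = c + 1; r < k; ++r) {
      double f = A[r * k + c] / d;
      if (f == 0.0) continue;
      for (int j = c; j < k; ++j) A[r * k + j] -= f * A[c * k + j];
      b[r] -= f * b[c];
    }
  }
  for (int c = k - 1; c >= 0; --c) {
    double v = b[c];
    for (int j = c + 1; j < k; ++j) v -= A[c * k + j] * b[j];
    b[c] = v / A[c * k + c];
  }
  return true;
}

// closed-form solve of a symmetric 3x3 system via the adjugate;
// returns false when the matrix is numerically singular
static inline bool solve_sym3(const double *A, const double *b, double *x) {
  const double a00 = A[0], a01 = A[1], a02 = A[2];
  const double a11 = A[4], a12 = A[5], a22 = A[8];
  const double c00 = a11 * a22 - a12 * a12;
  const double c01 = a02 * a12 - a01 * a22;
  const double c02 = a01 * a12 - a02 * a11;
  const double det = a00 * c00 + a01 * c01 + a02 * c02;
  if (std::fabs(det) < 1e-300) return false;
  const double c11 = a00 * a22 - a02 * a02;
  const double c12 = a02 * a01 - a00 * a12;
  const double c22 = a00 * a11 - a01 * a01;
  x[0] = (c00 * b[0] + c01 * b[1] + c02 * b[2]) / det;
  x[1] = (c01 * b[0] + c11 * b[1] + c12 * b[2]) / det;
  x[2] = (c02 * b[0] + c12 * b[1] + c22 * b[2]) / det;
  return true;
}

// [[Rcpp::export(name = ".subset_loocv_cpp")]]
List subset_loocv_cpp(NumericMatrix X, IntegerVector y, IntegerMatrix subsets,
                      double shrinkage) {
  const int n = X.nrow();
  const int k = subsets.nrow();
  const int m = subsets.ncol();
  int n1 = 0;
  for (int i = 0; i < n; ++i) n1 += (y[i] == 1);
  const int n0 = n - n1;
  if (n1 < 2 || n0 < 2) stop("each class needs at least two samples");

  NumericVector acc(m), sep(m);
  std::vector<double> Xs(n * k);
  std::vector<double> s1(k), s0(k), OP1(k * k), OP0(k * k);
  std::vector<double> mu1(k), mu0(k), S(k * k), A(k * k), b(k);

  for (int s = 0; s < m; ++s) {
    for (int j = 0; j < k; ++j) {
      const int col = subsets(j, s);
      for (int i = 0; i < n; ++i) Xs[j * n + i] = X(i, col);
    }
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(s0.begin(), s0.end(), 0.0);
    std::fill(OP1.begin(), OP1.end(), 0.0);
    std::fill(OP0.begin(), OP0.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      std::vector<double> &sv = (y[i] == 1) ? s1 : s0;
      std::vector<double> &op = (y[i] == 1) ? OP1 : OP0;
      for (int a = 0; a < k; ++a) {
        const double xa = Xs[a * n + i];
        sv[a] += xa;
        for (int bq = a; bq < k; ++bq) op[a * k + bq] += xa * Xs[bq * n + i];
      }
    }
    for (int a = 0; a < k; ++a)
      for (int bq = 0; bq < a; ++bq) {
        OP1[a * k + bq] = OP1[bq * k + a];
        OP0[a * k + bq] = OP0[bq * k + a];
      }

    // full-fit Fisher separation for tie-breaking
    for (int a = 0; a < k; ++a) { mu1[a] = s1[a] / n1; mu0[a] = s0[a] / n0; }
    double tr = 0.0;
    for (int a = 0; a < k; ++a)
      for (int bq = 0; bq < k; ++bq) {
        double sc = OP1[a * k + bq] - n1 * mu1[a] * mu1[bq] +
                    OP0[a * k + bq] - n0 * mu0[a] * mu0[bq];
        S[a * k + bq] = sc / (n - 2);
        if (a == bq) tr += S[a * k + bq];
      }
    for (int a = 0; a < k; ++a)
      for (int bq = 0; bq < k; ++bq) {
        A[a * k + bq] = (1.0 - shrinkage) * S[a * k + bq];
        if (a == bq) A[a * k + bq] += shrinkage * tr / k;
      }
    for (int a = 0; a < k; ++a) b[a] = mu1[a] - mu0[a];
    double J = NA_REAL;
    if (k == 3) {
      double x3[3];
      if (solve_sym3(A.data(), b.data(), x3))
        J = x3[0] * b[0] + x3[1] * b[1] + x3[2] * b[2];
    } else {
      std::vector<double> Acpy(A), bcpy(b);
      if (solve_spd(Acpy, bcpy, k)) {
        J = 0.0;
        for (int a = 0; a < k; ++a) J += bcpy[a] * (mu1[a] - mu0[a]);
      }
    }
    sep[s] = J;

    // LOOCV
    int correct = 0;
    for (int i = 0; i < n; ++i) {
      const bool pos = (y[i] == 1);
      const int m1 = pos ? n1 - 1 : n1;
      const int m0 = pos ? n0 : n0 - 1;
      if (m1 == 0 || m0 == 0) {
        // degenerate fold: majority of the remaining class
        const bool pred = (m1 >= m0);
        if (pred == pos) ++correct;
        continue;
      }
      for (int a = 0; a < k; ++a) {
        const double xa = Xs[a * n + i];
        mu1[a] = (s1[a] - (pos ? xa : 0.0)) / m1;
        mu0[a] = (s0[a] - (pos ? 0.0 : xa)) / m0;
      }
      double trf = 0.0;
      for (int a = 0; a < k; ++a)
        for (int bq = a; bq < k; ++bq) {
          const double xa = Xs[a * n + i], xb = Xs[bq * n + i];
          double sc1 = OP1[a * k + bq] - (pos ? xa * xb : 0.0) - m1 * mu1[a] * mu1[bq];
          double sc0 = OP0[a * k + bq] - (pos ? 0.0 : xa * xb) - m0 * mu0[a] * mu0[bq];
          double v = (sc1 + sc0) / (n - 3);
          S[a * k + bq] = v;
          S[bq * k + a] = v;
          if (a == bq) trf += v;
        }
      for (int a = 0; a < k; ++a)
        for (int bq = 0; bq < k; ++bq) {
          A[a * k + bq] = (1.0 - shrinkage) * S[a * k + bq];
          if (a == bq) A[a * k + bq] += shrinkage * trf / k;
        }
      for (int a = 0; a < k; ++a) b[a] = mu1[a] - mu0[a];
      double wbuf[3];
      const double *w;
      if (k == 3) {
        if (!solve_sym3(A.data(), b.data(), wbuf)) continue;
        w = wbuf;
      } else {
        if (!solve_spd(A, b, k)) continue;  // unscorable fold counts as error
        w = b.data();
      }
      double score = 0.0, thr = 0.0;
      for (int a = 0; a < k; ++a) {
        score += w[a] * Xs[a * n + i];
        thr += w[a] * 0.5 * (mu1[a] + mu0[a]);
      }
      const bool pred = (score >= thr);
      if (pred == pos) ++correct;
    }
    acc[s] = static_cast<double>(correct) / n;
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["accuracy"] = acc, _["separation"] = sep);
}
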