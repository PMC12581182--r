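#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Streaming O(n^2) distance-covariance statistics for univariate x, y.
// Uses the double-centering identity
//   mean(A o B) = mean(ab) - 2 * mean_j(abar_j * bbar_j) + abar * bbar
// so the full n x n centred matrices are never materialised.
// Returns c(dcov2_xy, dvar2_x, dvar2_y).
// [[Rcpp::export(name = ".dcovStats")]]
NumericVector dcov_stats(NumericVector x, NumericVector y) {
  const R_xlen_t n = x.size();
  std::vector<double> arow(n, 0.0), brow(n, 0.0);
  double Sab = 0.0, Saa = 0.0, Sbb = 0.0;
  for (R_xlen_t j = 0; j < n; ++j) {
    for (R_xlen_t k = j + 1; k < n; ++k) {
      const double a = std::fabs(x[j] - x[k]);
      const double b = std::fabs(y[j] - y[k]);
      arow[j] += a; arow[k] += a;
      brow[j] += b; brow[k] += b;
      Sab += 2.0 * a * b;
      Saa += 2.0 * a * a;
      Sbb += 2.0 * b * b;
    }
  }
  double Sa = 0.0, Sb = 0.0, Sarbr = 0.0, Sar2 = 0.0, Sbr2 = 0.0;
  for (R_xlen_t j = 0; j < n; ++j) {
    Sa += arow[j]; Sb += brow[j];
    Sarbr += arow[j] * brow[j];
    Sar2 += arow[j] * arow[j];
    Sbr2 += brow[j] * brow[j];
  }
  const double n2 = (double)n * n, n3 = n2 * n, n4 = n3 * n;
  NumericVector out(3);
  out[0] = Sab / n2 - 2.0 * Sarbr / n3 + (Sa * Sb) / n4;
  out[1] = Saa / n2 - 2.0 * Sar2 / n3 + (Sa * Sa) / n4;
  out[2] = Sbb / n2 - 2.0 * Sbr2 / n3 + (Sb * Sb) / n4;
  return out;
}

// dCov^2 between a fixed centred matrix A and B[p, p] for each
// permutation p (columns of P, 1-based indices from R). dVar terms are
// permutation-invariant so only the cross term is needed.
// [[Rcpp::export(name = ".dcovPerm")]]
NumericVector dcov_perm(NumericMatrix A, NumericMatrix B, IntegerMatrix P) {
  const int n = A.nrow(), m = P.ncol();
  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      const int pj = P(j, t) - 1;
      for (int k = 0; k < n; ++k)
        s += A(j, k) * B(pj, P(k, t) - 1);
    }
    out[t] = s / ((double)n * n);
  }
  return out;
}
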