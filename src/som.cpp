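#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Online self-organising map training.
//   data:   cells x markers
//   codes:  initial codebook, nodes x markers (modified copy returned)
//   gridxy: nodes x 2 grid coordinates (row, col)
//   order:  1-based presentation order of cells, length = total updates
//           (rlen passes through the data, drawn in R for seed control)
//   radii:  neighbourhood radius per update (linear decay, in grid units)
//   alphas: learning rate per update
// Gaussian neighbourhood weight exp(-d2 / (2 sigma^2)) on the grid,
// sigma floored to avoid division by zero at the end of training.
// [[Rcpp::export(name = ".somTrain")]]
NumericMatrix som_train(NumericMatrix data, NumericMatrix codes,
                        NumericMatrix gridxy, IntegerVector order,
                        NumericVector radii, NumericVector alphas) {
  const int nnodes = codes.nrow(), nmark = codes.ncol();
  NumericMatrix cb = clone(codes);
  const R_xlen_t nupd = order.size();
  for (R_xlen_t t = 0; t < nupd; ++t) {
    const int i = order[t] - 1;
    // best-matching unit (ties: lowest index)
    int bmu = 0; double best = R_PosInf;
    for (int j = 0; j < nnodes; ++j) {
      double d2 = 0.0;
      for (int m = 0; m < nmark; ++m) {
        const double diff = data(i, m) - cb(j, m);
        d2 += diff * diff;
      }
      if (d2 < best) { best = d2; bmu = j; }
    }
    const double sigma = std::max(radii[t], 1e-3);
    const double denom = 2.0 * sigma * sigma;
    const double alpha = alphas[t];
    const double bx = gridxy(bmu, 0), by = gridxy(bmu, 1);
    for (int j = 0; j < nnodes; ++j) {
      const double dx = gridxy(j, 0) - bx, dy = gridxy(j, 1) - by;
      const double h = alpha * std::exp(-(dx * dx + dy * dy) / denom);
      if (h < 1e-12) continue;
      for (int m = 0; m < nmark; ++m)
        cb(j, m) += h * (data(i, m) - cb(j, m));
    }
  }
  return cb;
}

// Best-matching unit per cell: argmin Euclidean distance, ties broken by
// the lowest node index (strict < keeps the first minimum).
// [[Rcpp::export(name = ".somAssign")]]
IntegerVector som_assign(NumericMatrix data, NumericMatrix codes) {
  const int n = data.nrow(), nnodes = codes.nrow(), nmark = codes.ncol();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int bmu = 0; double best = R_PosInf;
    for (int j = 0; j < nnodes; ++j) {
      double d2 = 0.0;
      for (int m = 0; m < nmark; ++m) {
        const double diff = data(i, m) - codes(j, m);
        d2 += diff * diff;
      }
      if (d2 < best) { best = d2; bmu = j; }
    }
    out[i] = bmu + 1;
  }
  return out;
}
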