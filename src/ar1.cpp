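#include <Rcpp.h>
using namespace Rcpp;

// First-order autoregressive recursion x[,t] = phi * x[,t-1] + e[,t],
// one independent filter state per row. Columns are time (contiguous in
// R's column-major layout, so the inner loop is sequential memory).
// [[Rcpp::export]]
NumericMatrix ar1_filter_rows(NumericMatrix e, double phi) {
  int nr = e.nrow(), nc = e.ncol();
  NumericMatrix x = clone(e);
  for (int t = 1; t < nc; ++t) {
    double *prev = &x(0, t - 1), *cur = &x(0, t);
    for (int r = 0; r < nr; ++r) cur[r] += phi * prev[r];
  }
  return x;
}
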