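#include <Rcpp.h>
using namespace Rcpp;

// Accumulate precomputed blob kernels onto a field at integer centres.
// kernels: list of square odd-sized matrices (one per orientation);
// ci, cj: 1-based centre coordinates (may lie outside the field, in
// which case the overhanging part of the kernel is clipped);
// kid: 1-based kernel index per blob.
// [[Rcpp::export]]
NumericMatrix clb_splat(int nrow, int ncol,
                        IntegerVector ci, IntegerVector cj,
                        IntegerVector kid, List kernels) {
  NumericMatrix field(nrow, ncol);
  double *fp = REAL(field);
  int nb = ci.size();
  for (int b = 0; b < nb; ++b) {
    NumericMatrix K = kernels[kid[b] - 1];
    const double *kp = REAL(K);
    int knr = K.nrow(), knc = K.ncol();
    int kh = (knr - 1) / 2;
    int r0 = ci[b] - 1 - kh, c0 = cj[b] - 1 - kh;
    int rlo = std::max(0, -r0), rhi = std::min(knr - 1, nrow - 1 - r0);
    int clo = std::max(0, -c0), chi = std::min(knc - 1, ncol - 1 - c0);
    if (rlo > rhi) continue;
    for (int c = clo; c <= chi; ++c) {
      double *fcol = fp + (size_t)(c0 + c) * nrow + (r0 + rlo);
      const double *kcol = kp + (size_t)c * knr + rlo;
      int len = rhi - rlo + 1;
      for (int r = 0; r < len; ++r) fcol[r] += kcol[r];
    }
  }
  return field;
}
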