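#include <Rcpp.h>
using namespace Rcpp;

// PLI matrix from per-channel sin/cos of instantaneous phase.
// sign(sin(phi_i - phi_j)) = sign(sin_i cos_j - cos_i sin_j); sign(0) = 0.
// Matrices are samples x channels so the inner loop is stride-1.
// [[Rcpp::export(name = ".pli_matrix_sc")]]
NumericMatrix pli_matrix_sc(NumericMatrix sinph, NumericMatrix cosph) {
  const int n = sinph.nrow();   // samples
  const int nc = sinph.ncol();  // channels
  NumericMatrix out(nc, nc);
  for (int i = 0; i < nc - 1; ++i) {
    const double* si = &sinph(0, i);
    const double* ci = &cosph(0, i);
    for (int j = i + 1; j < nc; ++j) {
      const double* sj = &sinph(0, j);
      const double* cj = &cosph(0, j);
      double acc = 0.0;
      for (int t = 0; t < n; ++t) {
        const double d = si[t] * cj[t] - ci[t] * sj[t];
        acc += (d > 0.0) - (d < 0.0);
      }
      const double v = std::abs(acc) / n;
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}
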