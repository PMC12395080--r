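#include <Rcpp.h>
using namespace Rcpp;

// Pairwise phase-lag-index accumulation for one epoch and band.
// U, V: timepoints x channels real and imaginary parts of the band-limited
// analytic signal (normalization is irrelevant: only the sign of
// Im(z_a * conj(z_b)) per sample enters). Returns the upper-triangular
// matrix of |mean_t sign(Im(z_a conj(z_b)))|.
// [[Rcpp::export]]
NumericMatrix pli_pair_sums(NumericMatrix U, NumericMatrix V) {
  const int nt = U.nrow(), nch = U.ncol();
  NumericMatrix out(nch, nch);
  for (int a = 0; a < nch - 1; ++a) {
    const double* ua = &U(0, a);
    const double* va = &V(0, a);
    for (int b = a + 1; b < nch; ++b) {
      const double* ub = &U(0, b);
      const double* vb = &V(0, b);
      double s = 0.0;
      for (int t = 0; t < nt; ++t) {
        const double x = vb[t] * ua[t] - ub[t] * va[t];
        s += (x > 0.0) - (x < 0.0);
      }
      out(a, b) = std::abs(s) / nt;
    }
  }
  return out;
}
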