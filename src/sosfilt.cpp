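#include <Rcpp.h>
using namespace Rcpp;

// One forward pass of a cascade of biquad sections (direct form II
// transposed). sos rows are (b0, b1, b2, a1, a2) with a0 = 1. Each
// section's internal state is initialised to its step-response steady
// state scaled by the first sample, so a constant input passes through
// with no start-up transient (the same idea as scipy's lfilter_zi).
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericVector x, NumericMatrix sos) {
  const int n = x.size();
  const int m = sos.nrow();
  NumericVector y = clone(x);
  for (int s = 0; s < m; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 3), a2 = sos(s, 4);
    const double den = 1.0 + a1 + a2;
    // DC gain of the section; den == 0 cannot occur for a stable section
    const double h1 = (den != 0.0) ? (b0 + b1 + b2) / den : 0.0;
    double z1 = (h1 - b0) * y[0];
    double z2 = (b2 - a2 * h1) * y[0];
    for (int i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}
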