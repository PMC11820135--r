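#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed biquad with explicit initial state.
// b, a are length-3 coefficient vectors with a[0] == 1.
// [[Rcpp::export]]
NumericVector biquad_filter_cpp(NumericVector x, NumericVector b,
                                NumericVector a, NumericVector zi) {
  int n = x.size();
  NumericVector y(n);
  double z1 = zi[0], z2 = zi[1];
  double b0 = b[0], b1 = b[1], b2 = b[2], a1 = a[1], a2 = a[2];
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b0 * xi + z1;
    z1 = b1 * xi - a1 * yi + z2;
    z2 = b2 * xi - a2 * yi;
    y[i] = yi;
  }
  return y;
}
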