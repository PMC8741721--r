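// Direct-form-II-transposed IIR filter with caller-supplied initial
// state; the R wrapper builds the forward-backward zero-phase filter
// (odd signal extension + steady-state initial conditions).
#include <Rcpp.h>

// [[Rcpp::export(name = ".iir_filter_cpp")]]
Rcpp::NumericVector iir_filter_cpp(const Rcpp::NumericVector& b,
                                   const Rcpp::NumericVector& a,
                                   const Rcpp::NumericVector& x,
                                   const Rcpp::NumericVector& zi) {
  const int n = x.size();
  const int order = b.size() - 1;  // a and b normalized to equal length
  Rcpp::NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());
  z.resize(order, 0.0);
  for (int i = 0; i < n; ++i) {
    double yi = b[0] * x[i] + (order > 0 ? z[0] : 0.0);
    for (int k = 0; k < order - 1; ++k) {
      z[k] = b[k + 1] * x[i] + z[k + 1] - a[k + 1] * yi;
    }
    if (order > 0) z[order - 1] = b[order] * x[i] - a[order] * yi;
    y[i] = yi;
  }
  return y;
}
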