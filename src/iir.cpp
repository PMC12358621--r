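#include <Rcpp.h>

// Direct-form II transposed IIR filter with explicit initial conditions.
// b and a must be the same length with a[0] == 1 (normalised by the caller).
// zi has length(b) - 1 and is the delay-line state, typically the
// steady-state response scaled by the first sample so that forward-backward
// filtering starts transient-free at the padded signal edges.
// [[Rcpp::export]]
Rcpp::NumericVector iir_filter_zi(Rcpp::NumericVector b, Rcpp::NumericVector a,
                                  Rcpp::NumericVector x, Rcpp::NumericVector zi) {
  const int n = x.size();
  const int nf = b.size();
  if (a.size() != nf) Rcpp::stop("b and a must have equal length");
  if (zi.size() != nf - 1) Rcpp::stop("zi must have length(b) - 1");
  std::vector<double> z(zi.begin(), zi.end());
  Rcpp::NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int j = 0; j < nf - 2; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    z[nf - 2] = b[nf - 1] * xi - a[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}
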