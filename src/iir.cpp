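#include <Rcpp.h>

// Direct-form IIR filter y[t] = sum_j b[j] x[t-j] - sum_j a[j] y[t-j],
// zero initial state, applied column-wise. a[0] is assumed 1 (butter
// coefficients are normalised).
// [[Rcpp::export(name = ".iir_filter")]]
Rcpp::NumericMatrix iir_filter(Rcpp::NumericVector b, Rcpp::NumericVector a,
                               Rcpp::NumericMatrix x) {
  const int n = x.nrow(), m = x.ncol();
  const int nb = b.size(), na = a.size();
  Rcpp::NumericMatrix y(n, m);
  for (int c = 0; c < m; ++c) {
    const double* xc = &x(0, c);
    double* yc = &y(0, c);
    for (int t = 0; t < n; ++t) {
      double acc = 0.0;
      const int jb = t + 1 < nb ? t + 1 : nb;
      for (int j = 0; j < jb; ++j) acc += b[j] * xc[t - j];
      const int ja = t + 1 < na ? t + 1 : na;
      for (int j = 1; j < ja; ++j) acc -= a[j] * yc[t - j];
      yc[t] = acc;
    }
  }
  return y;
}
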