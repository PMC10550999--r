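#include <Rcpp.h>
using namespace Rcpp;

// IIR (ARMA) filter, direct form II transposed. Coefficients as from
// signal::butter; a[0] need not be 1. Keeps multi-minute 240-576 kHz tag
// audio tractable: one pass is O(n * order).
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nw = std::max(nb, na);
  std::vector<double> bb(nw, 0.0), aa(nw, 0.0), z(nw - 1, 0.0);
  const double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + (nw > 1 ? z[0] : 0.0);
    for (int j = 0; j < nw - 2; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (nw > 1)
      z[nw - 2] = bb[nw - 1] * xi - aa[nw - 1] * yi;
    y[i] = yi;
  }
  return y;
}
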