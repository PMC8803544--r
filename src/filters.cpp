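#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit initial state.
// b and a must have equal length (pad with zeros in R) and a[0] == 1.
// zi has length(b) - 1; pass zeros for a quiescent start.
// [[Rcpp::export]]
NumericVector filter_df2t(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  const int n = x.size();
  const int nc = b.size();
  if (a.size() != nc) stop("b and a must have equal length");
  if (zi.size() != nc - 1) stop("zi must have length(b) - 1");
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (nc > 1 ? z[0] : 0.0);
    for (int j = 0; j + 2 < nc; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    if (nc > 1) z[nc - 2] = b[nc - 1] * xi - a[nc - 1] * yi;
    y[i] = yi;
  }
  return y;
}
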