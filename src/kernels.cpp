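#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with optional initial state.
// a[0] must be non-zero; coefficients are normalized internally.
// [[Rcpp::export]]
NumericVector cpp_iir_filter(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nfilt = std::max(nb, na);
  std::vector<double> bn(nfilt, 0.0), an(nfilt, 0.0);
  double a0 = a[0];
  if (a0 == 0.0) stop("a[1] must be non-zero");
  for (int i = 0; i < nb; ++i) bn[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) an[i] = a[i] / a0;
  int n = x.size();
  NumericVector y(n);
  std::vector<double> z(nfilt - 1, 0.0);
  if (zi.size() > 0) {
    if ((int)zi.size() != nfilt - 1) stop("zi has wrong length");
    for (int i = 0; i < nfilt - 1; ++i) z[i] = zi[i];
  }
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bn[0] * xi + (nfilt > 1 ? z[0] : 0.0);
    for (int j = 0; j < nfilt - 2; ++j)
      z[j] = bn[j + 1] * xi + z[j + 1] - an[j + 1] * yi;
    if (nfilt > 1)
      z[nfilt - 2] = bn[nfilt - 1] * xi - an[nfilt - 1] * yi;
    y[i] = yi;
  }
  return y;
}

// Indices (1-based) of strict local maxima: x[i-1] < x[i] > x[i+1].
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector x) {
  int n = x.size();
  std::vector<int> idx;
  for (int i = 1; i + 1 < n; ++i) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) idx.push_back(i + 1);
  }
  return wrap(idx);
}

// Topographic prominence of each peak: walk out on both sides until a
// strictly higher sample or the series edge; base on each side is the
// minimum encountered; prominence = height - max(left base, right base).
// [[Rcpp::export]]
NumericVector cpp_peak_prominence(NumericVector x, IntegerVector peaks) {
  int n = x.size(), np = peaks.size();
  NumericVector prom(np);
  for (int k = 0; k < np; ++k) {
    int p = peaks[k] - 1;
    double h = x[p];
    double lmin = h, rmin = h;
    for (int j = p - 1; j >= 0; --j) {
      if (x[j] > h) break;
      if (x[j] < lmin) lmin = x[j];
    }
    for (int j = p + 1; j < n; ++j) {
      if (x[j] > h) break;
      if (x[j] < rmin) rmin = x[j];
    }
    prom[k] = h - std::max(lmin, rmin);
  }
  return prom;
}
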