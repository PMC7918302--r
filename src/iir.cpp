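#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial conditions.
// a[0] must be non-zero; coefficients are normalized internally.
// [[Rcpp::export]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         Nullable<NumericVector> zi = R_NilValue) {
  int n = std::max(b.size(), a.size());
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  double a0 = a[0];
  if (a0 == 0.0) stop("a[0] must be non-zero");
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i] / a0;
  std::vector<double> z(n - 1, 0.0);
  if (zi.isNotNull()) {
    NumericVector z0(zi);
    if (z0.size() != n - 1) stop("zi must have length max(length(a), length(b)) - 1");
    for (int i = 0; i < n - 1; ++i) z[i] = z0[i];
  }
  int nx = x.size();
  NumericVector y(nx);
  for (int i = 0; i < nx; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (n > 1 ? z[0] : 0.0);
    for (int j = 0; j < n - 2; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (n > 1)
      z[n - 2] = bb[n - 1] * xi - aa[n - 1] * yi;
    y[i] = yi;
  }
  return y;
}

// Cascaded second-order sections (direct-form II transposed) with optional
// per-section initial conditions (n_sections x 2 matrix).
// [[Rcpp::export]]
NumericVector sos_filter(NumericMatrix sos, NumericVector x,
                         Nullable<NumericMatrix> zi = R_NilValue) {
  int ns = sos.nrow(), nx = x.size();
  if (sos.ncol() != 6) stop("sos must have 6 columns");
  std::vector<double> z1(ns, 0.0), z2(ns, 0.0);
  if (zi.isNotNull()) {
    NumericMatrix z0(zi);
    if (z0.nrow() != ns || z0.ncol() != 2) stop("zi must be n_sections x 2");
    for (int s = 0; s < ns; ++s) { z1[s] = z0(s, 0); z2[s] = z0(s, 1); }
  }
  NumericVector y(nx);
  for (int i = 0; i < nx; ++i) {
    double v = x[i];
    for (int s = 0; s < ns; ++s) {
      double a0 = sos(s, 3);
      double b0 = sos(s, 0) / a0, b1 = sos(s, 1) / a0, b2 = sos(s, 2) / a0;
      double a1 = sos(s, 4) / a0, a2 = sos(s, 5) / a0;
      double w = b0 * v + z1[s];
      z1[s] = b1 * v + z2[s] - a1 * w;
      z2[s] = b2 * v - a2 * w;
      v = w;
    }
    y[i] = v;
  }
  return y;
}
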