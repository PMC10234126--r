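#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter, a[0] assumed 1 (normalized by the
// caller). Single forward pass; the R wrapper composes two passes with
// reflection padding for zero-phase filtering of long traces.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i <= nz; ++i) {
    if (i < nb) bb[i] = b[i];
    if (i < na) aa[i] = a[i];
  }
  NumericVector y(n);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  if (nz == 4) {
    // unrolled 4th-order path (the package's Butterworth default); keeping
    // the state in registers makes the recursion ~10x faster than the
    // generic indexed loop
    const double b0 = bb[0], b1 = bb[1], b2 = bb[2], b3 = bb[3], b4 = bb[4];
    const double a1 = aa[1], a2 = aa[2], a3 = aa[3], a4 = aa[4];
    double z0 = 0, z1 = 0, z2 = 0, z3 = 0;
    for (int i = 0; i < n; ++i) {
      const double xi = xp[i];
      const double yi = b0 * xi + z0;
      z0 = b1 * xi + z1 - a1 * yi;
      z1 = b2 * xi + z2 - a2 * yi;
      z2 = b3 * xi + z3 - a3 * yi;
      z3 = b4 * xi - a4 * yi;
      yp[i] = yi;
    }
    return y;
  }
  for (int i = 0; i < n; ++i) {
    const double xi = xp[i];
    const double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nz - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    yp[i] = yi;
  }
  return y;
}

// Forward-backward (zero-phase) application of the same IIR filter without
// intermediate reversal copies: the backward pass simply iterates the
// recursion from the end. States start at zero; the caller handles edge
// padding and DC offsets.
// [[Rcpp::export]]
NumericVector filtfilt_cpp(NumericVector b, NumericVector a, NumericVector x) {
  NumericVector y = iir_filter_cpp(b, a, x);
  const int nb = b.size(), na = a.size(), n = y.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i <= nz; ++i) {
    if (i < nb) bb[i] = b[i];
    if (i < na) aa[i] = a[i];
  }
  double* yp = REAL(y);
  if (nz == 4) {
    const double b0 = bb[0], b1 = bb[1], b2 = bb[2], b3 = bb[3], b4 = bb[4];
    const double a1 = aa[1], a2 = aa[2], a3 = aa[3], a4 = aa[4];
    double z0 = 0, z1 = 0, z2 = 0, z3 = 0;
    for (int i = n - 1; i >= 0; --i) {
      const double xi = yp[i];
      const double yi = b0 * xi + z0;
      z0 = b1 * xi + z1 - a1 * yi;
      z1 = b2 * xi + z2 - a2 * yi;
      z2 = b3 * xi + z3 - a3 * yi;
      z3 = b4 * xi - a4 * yi;
      yp[i] = yi;
    }
    return y;
  }
  std::vector<double> z(nz, 0.0);
  for (int i = n - 1; i >= 0; --i) {
    const double xi = yp[i];
    const double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nz - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    yp[i] = yi;
  }
  return y;
}

// Sliding root-mean-square with a centered window and edge shrinkage:
// output has the same length as the input.
// [[Rcpp::export]]
NumericVector sliding_rms_cpp(NumericVector x, int window) {
  const int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  if (window < 1) window = 1;
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i] * x[i];
  const int half = window / 2;
  for (int i = 0; i < n; ++i) {
    int lo = i - half; if (lo < 0) lo = 0;
    int hi = i - half + window; if (hi > n) hi = n;
    out[i] = std::sqrt((cs[hi] - cs[lo]) / (hi - lo));
  }
  return out;
}
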