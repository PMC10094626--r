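#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// half-sample symmetric reflection: index -1 maps to 0, n maps to n-1
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Separable correlation of a matrix with a symmetric 1-D kernel along both
// axes, with reflective (half-sample symmetric) boundary handling. The kernel
// length must be odd; its centre tap is at (len-1)/2.
// [[Rcpp::export]]
NumericMatrix cpp_sep_convolve_reflect(NumericMatrix x, NumericVector kernel) {
  const int nr = x.nrow(), nc = x.ncol(), k = kernel.size();
  if (k % 2 == 0) stop("kernel length must be odd");
  const int r = (k - 1) / 2;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double* kp = kernel.begin();

  // along columns (vertical pass); interior rows use direct indexing
  for (int j = 0; j < nc; ++j) {
    const double* col = &x(0, j);
    double* tcol = &tmp(0, j);
    const int lo = std::min(r, nr), hi = std::max(nr - r, lo);
    for (int i = 0; i < lo; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) acc += kp[t + r] * col[reflect_idx(i + t, nr)];
      tcol[i] = acc;
    }
    for (int i = lo; i < hi; ++i) {
      double acc = 0.0;
      const double* p = col + i - r;
      for (int t = 0; t < k; ++t) acc += kp[t] * p[t];
      tcol[i] = acc;
    }
    for (int i = hi; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) acc += kp[t + r] * col[reflect_idx(i + t, nr)];
      tcol[i] = acc;
    }
  }
  // along rows (horizontal pass); accumulate column by column to stay
  // cache-friendly in the column-major layout
  std::fill(out.begin(), out.end(), 0.0);
  for (int j = 0; j < nc; ++j) {
    double* ocol = &out(0, j);
    for (int t = -r; t <= r; ++t) {
      const double w = kp[t + r];
      const double* scol = &tmp(0, reflect_idx(j + t, nc));
      for (int i = 0; i < nr; ++i) ocol[i] += w * scol[i];
    }
  }
  return out;
}

// Row-wise medians (used for the per-pixel-median base frame; rows are pixels,
// columns are sampled frames).
// [[Rcpp::export]]
NumericVector cpp_row_medians(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nr);
  std::vector<double> buf(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) buf[j] = x(i, j);
    const int mid = nc / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double m = buf[mid];
    if (nc % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + mid);
      m = 0.5 * (m + lo);
    }
    out[i] = m;
  }
  return out;
}
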