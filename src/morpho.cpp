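// Grayscale morphological reconstruction by alternating raster sweeps
// (8-connected), used by the extended-maxima H-transform.

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_gray_reconstruct(NumericMatrix seed, NumericMatrix mask,
                                   int max_sweeps = 256) {
  const int nx = seed.nrow(), ny = seed.ncol();
  NumericMatrix rec(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      rec(i, j) = std::min(seed(i, j), mask(i, j));

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool changed = false;
    // forward pass
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double m = rec(i, j);
        if (i > 0) m = std::max(m, rec(i - 1, j));
        if (j > 0) m = std::max(m, rec(i, j - 1));
        if (i > 0 && j > 0) m = std::max(m, rec(i - 1, j - 1));
        if (i < nx - 1 && j > 0) m = std::max(m, rec(i + 1, j - 1));
        m = std::min(m, mask(i, j));
        if (m > rec(i, j)) { rec(i, j) = m; changed = true; }
      }
    }
    // backward pass
    for (int j = ny - 1; j >= 0; --j) {
      for (int i = nx - 1; i >= 0; --i) {
        double m = rec(i, j);
        if (i < nx - 1) m = std::max(m, rec(i + 1, j));
        if (j < ny - 1) m = std::max(m, rec(i, j + 1));
        if (i < nx - 1 && j < ny - 1) m = std::max(m, rec(i + 1, j + 1));
        if (i > 0 && j < ny - 1) m = std::max(m, rec(i - 1, j + 1));
        m = std::min(m, mask(i, j));
        if (m > rec(i, j)) { rec(i, j) = m; changed = true; }
      }
    }
    if (!changed) break;
  }
  return rec;
}
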