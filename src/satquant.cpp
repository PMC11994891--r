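#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Edge-replicated index into [0, n)
static inline int clampi(int i, int n) {
  return i < 0 ? 0 : (i >= n ? n - 1 : i);
}

// Spatial convolution with edge replication. The kernel is flipped (true
// convolution); symmetric kernels are unaffected. Returns unclamped doubles;
// rounding/clamping policy lives in R.
// [[Rcpp::export]]
NumericMatrix cpp_convolve(NumericMatrix img, NumericMatrix kernel) {
  const int H = img.nrow(), W = img.ncol();
  const int kh = kernel.nrow(), kw = kernel.ncol();
  const int cr = kh / 2, cc = kw / 2;
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int dj = -cc; dj <= cc; ++dj) {
        const int sj = clampi(j - dj, W);
        for (int di = -cr; di <= cr; ++di) {
          const int si = clampi(i - di, H);
          acc += img(si, sj) * kernel(cr + di, cc + dj);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Median filter over a (2r+1)x(2r+1) edge-replicated window.
// [[Rcpp::export]]
IntegerMatrix cpp_median_filter(IntegerMatrix img, int radius) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix out(H, W);
  const int side = 2 * radius + 1;
  std::vector<int> buf(side * side);
  const size_t mid = buf.size() / 2;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      size_t k = 0;
      for (int dj = -radius; dj <= radius; ++dj) {
        const int sj = clampi(j + dj, W);
        for (int di = -radius; di <= radius; ++di) {
          buf[k++] = img(clampi(i + di, H), sj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(i, j) = buf[mid];
    }
  }
  return out;
}

// Connected-component labeling, 4- or 8-connectivity, labels assigned in
// raster order (row by row) of the first-encountered pixel of each component.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W); // zero-initialized
  static const int d8i[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int d8j[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int d4i[4] = {-1, 0, 0, 1};
  static const int d4j[4] = {0, -1, 1, 0};
  const int nd = (connectivity == 8) ? 8 : 4;
  const int *ddi = (connectivity == 8) ? d8i : d4i;
  const int *ddj = (connectivity == 8) ? d8j : d4j;

  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      while (!stack.empty()) {
        const std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < nd; ++k) {
          const int ni = p.first + ddi[k], nj = p.second + ddj[k];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(std::make_pair(ni, nj));
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
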