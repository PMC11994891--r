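#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Exact grayscale erosion/dilation by a spherical-cap (ball) structuring
// element, used for rolling-ball background estimation.
//
// The ball of radius r decomposes by columns: for a horizontal offset dx the
// vertical profile is a circle cap of radius R = sqrt(r^2 - dx^2), with
// heights h(dy) = sqrt(R^2 - dy^2). So
//   erode(f)(i,j)  = min_dx  [ erode1d_R(f[, j+dx]) ](i)
// and the 2D transform reduces to 1D cap erosions of each column at r+1
// distinct radii plus a running min across columns.
//
// The 1D cap erosion e(y) = min_x f(x) - h(x - y) is computed by a lower
// envelope sweep (Felzenszwalb-style): the shifted curves
// v_x(y) = f(x) - h(y - x) are copies of the same convex function -h, so two
// of them cross at most once and takeover points (found by binary search,
// support expiry included) are ordered. Outside the image the window is
// clipped (identity-element padding), the usual convention for morphology
// at borders.

static const double INF = std::numeric_limits<double>::infinity();

struct CapEnvelope {
  int D;                    // integer support half-width
  std::vector<double> h;    // h[d] = sqrt(R^2 - d^2), d = 0..D
  std::vector<int> sx;      // stack: source index
  std::vector<int> sz;      // stack: takeover start
  void set_radius(double R) {
    D = static_cast<int>(std::floor(R));
    h.resize(D + 1);
    for (int d = 0; d <= D; ++d) h[d] = std::sqrt(R * R - static_cast<double>(d) * d);
  }
  inline double value(const double *g, int x, int y) const {
    const int d = y >= x ? y - x : x - y;
    return d <= D ? g[x] - h[d] : INF;
  }
  // smallest y in [lo, x1 + D + 1] where curve x2 (> x1) is <= curve x1;
  // at y = x1 + D + 1 curve x1 has expired, so success is guaranteed there
  int takeover(const double *g, int x1, int x2, int n) const {
    int lo = x2 - D;
    if (lo < 0) lo = 0;
    int hi = x1 + D + 1;
    if (hi > n) hi = n; // beyond the array nothing is evaluated
    while (lo < hi) {
      const int mid = lo + (hi - lo) / 2;
      if (value(g, x2, mid) <= value(g, x1, mid)) hi = mid; else lo = mid + 1;
    }
    return lo;
  }
  // e[y] = min_{|x-y|<=D, 0<=x<n} g[x] - h[|x-y|]
  void erode(const double *g, double *e, int n) {
    sx.clear(); sz.clear();
    for (int x = 0; x < n; ++x) {
      int z = sx.empty() ? 0 : takeover(g, sx.back(), x, n);
      while (!sx.empty() && z <= sz.back()) {
        sx.pop_back(); sz.pop_back();
        z = sx.empty() ? 0 : takeover(g, sx.back(), x, n);
      }
      sx.push_back(x); sz.push_back(z);
    }
    size_t k = 0;
    for (int y = 0; y < n; ++y) {
      while (k + 1 < sz.size() && sz[k + 1] <= y) ++k;
      e[y] = value(g, sx[k], y);
    }
  }
};

static void ball_transform(const NumericMatrix &src, NumericMatrix &dst,
                           int radius, bool dilate) {
  const int H = src.nrow(), W = src.ncol();
  const double r = static_cast<double>(radius);
  std::fill(dst.begin(), dst.end(), INF);

  std::vector<CapEnvelope> env(radius + 1);
  for (int a = 0; a <= radius; ++a) env[a].set_radius(std::sqrt(r * r - static_cast<double>(a) * a));

  std::vector<double> g(H), e(H);
  for (int c = 0; c < W; ++c) {
    const double *col = &src[static_cast<size_t>(c) * H];
    if (dilate) {
      for (int i = 0; i < H; ++i) g[i] = -col[i];
    } else {
      for (int i = 0; i < H; ++i) g[i] = col[i];
    }
    for (int a = 0; a <= radius; ++a) {
      const int j1 = c - a, j2 = c + a;
      if (j1 < 0 && j2 >= W) continue;
      env[a].erode(g.data(), e.data(), H);
      if (j1 >= 0) {
        double *out = &dst[static_cast<size_t>(j1) * H];
        for (int i = 0; i < H; ++i) if (e[i] < out[i]) out[i] = e[i];
      }
      if (a > 0 && j2 < W) {
        double *out = &dst[static_cast<size_t>(j2) * H];
        for (int i = 0; i < H; ++i) if (e[i] < out[i]) out[i] = e[i];
      }
    }
  }
  if (dilate) {
    for (R_xlen_t i = 0; i < dst.size(); ++i) dst[i] = -dst[i];
  }
}

// Rolling-ball background: grayscale opening (erosion then dilation) with
// the spherical-cap element of the given radius.
// [[Rcpp::export]]
NumericMatrix cpp_rolling_ball_background(NumericMatrix img, int radius) {
  NumericMatrix ero(img.nrow(), img.ncol());
  NumericMatrix bg(img.nrow(), img.ncol());
  ball_transform(img, ero, radius, false);
  ball_transform(ero, bg, radius, true);
  return bg;
}
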