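#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Watershed labeling of a grayscale landscape, flooding from its bright
// peaks (equivalently: flooding the inverted landscape from its regional
// minima). Shallow peaks are suppressed first with an h-maxima transform
// (morphological reconstruction by dilation of f - h under f, Vincent's
// hybrid raster/FIFO algorithm), so basins whose peak rises less than h
// gray levels above their saddle merge with a neighbor. The remaining
// regional maxima seed a deterministic priority flood (highest level first,
// FIFO within a level). 8-connectivity throughout.

static const int DI8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DJ8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

static void reconstruct_dilation(std::vector<double> &rec,
                                 const std::vector<double> &mask,
                                 int H, int W) {
  // forward raster pass
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double m = rec[i + j * H];
      // causal neighbors in column-major order: (i-1,j) and (i-1..i+1, j-1)
      if (i > 0) m = std::max(m, rec[(i - 1) + j * H]);
      if (j > 0) {
        for (int di = -1; di <= 1; ++di) {
          const int ni = i + di;
          if (ni >= 0 && ni < H) m = std::max(m, rec[ni + (j - 1) * H]);
        }
      }
      rec[i + j * H] = std::min(m, mask[i + j * H]);
    }
  }
  // backward raster pass + seed queue
  std::queue<int> fifo;
  for (int j = W - 1; j >= 0; --j) {
    for (int i = H - 1; i >= 0; --i) {
      double m = rec[i + j * H];
      if (i < H - 1) m = std::max(m, rec[(i + 1) + j * H]);
      if (j < W - 1) {
        for (int di = -1; di <= 1; ++di) {
          const int ni = i + di;
          if (ni >= 0 && ni < H) m = std::max(m, rec[ni + (j + 1) * H]);
        }
      }
      rec[i + j * H] = std::min(m, mask[i + j * H]);
      // enqueue if an anti-causal neighbor could still be raised
      const double v = rec[i + j * H];
      bool push = false;
      if (i < H - 1) {
        const int q = (i + 1) + j * H;
        if (rec[q] < v && rec[q] < mask[q]) push = true;
      }
      if (!push && j < W - 1) {
        for (int di = -1; di <= 1 && !push; ++di) {
          const int ni = i + di;
          if (ni >= 0 && ni < H) {
            const int q = ni + (j + 1) * H;
            if (rec[q] < v && rec[q] < mask[q]) push = true;
          }
        }
      }
      if (push) fifo.push(i + j * H);
    }
  }
  while (!fifo.empty()) {
    const int p = fifo.front();
    fifo.pop();
    const int pi = p % H, pj = p / H;
    for (int k = 0; k < 8; ++k) {
      const int ni = pi + DI8[k], nj = pj + DJ8[k];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      const int q = ni + nj * H;
      if (rec[q] < rec[p] && rec[q] < mask[q]) {
        rec[q] = std::min(rec[p], mask[q]);
        fifo.push(q);
      }
    }
  }
}

struct FloodEntry {
  double level;
  std::uint64_t order;
  int pixel;
  int label;
};
struct FloodCompare {
  bool operator()(const FloodEntry &a, const FloodEntry &b) const {
    if (a.level != b.level) return a.level < b.level; // max-heap on level
    return a.order > b.order;                         // FIFO within level
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed_labels(NumericMatrix img, double h) {
  const int H = img.nrow(), W = img.ncol();
  const int n = H * W;

  std::vector<double> rec(n), mask(n);
  for (int p = 0; p < n; ++p) mask[p] = img[p];
  for (int p = 0; p < n; ++p) rec[p] = img[p] - h;
  reconstruct_dilation(rec, mask, H, W);

  // regional maxima of rec: plateaus with no strictly higher neighbor
  IntegerMatrix lab(H, W); // 0 = unlabeled
  std::vector<int> plateau;
  int next_label = 0;
  std::vector<int> stack;
  for (int p = 0; p < n; ++p) {
    if (lab[p] != 0) continue;
    const double v = rec[p];
    bool is_max = true;
    plateau.clear();
    stack.clear();
    stack.push_back(p);
    lab[p] = -1; // visiting mark
    while (!stack.empty()) {
      const int q = stack.back();
      stack.pop_back();
      plateau.push_back(q);
      const int qi = q % H, qj = q / H;
      for (int k = 0; k < 8; ++k) {
        const int ni = qi + DI8[k], nj = qj + DJ8[k];
        if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
        const int r = ni + nj * H;
        if (rec[r] > v) is_max = false;
        else if (rec[r] == v && lab[r] == 0) {
          lab[r] = -1;
          stack.push_back(r);
        }
      }
    }
    if (is_max) {
      ++next_label;
      for (size_t t = 0; t < plateau.size(); ++t) lab[plateau[t]] = next_label;
    } else {
      // keep non-max plateaus marked so they are not re-flooded from every
      // member pixel (-2 = visited, not a maximum)
      for (size_t t = 0; t < plateau.size(); ++t) lab[plateau[t]] = -2;
    }
  }
  for (int p = 0; p < n; ++p) if (lab[p] == -2) lab[p] = 0;

  // priority flood from the seeds over the reconstructed landscape
  std::priority_queue<FloodEntry, std::vector<FloodEntry>, FloodCompare> pq;
  std::uint64_t counter = 0;
  for (int p = 0; p < n; ++p) {
    if (lab[p] <= 0) continue;
    const int pi = p % H, pj = p / H;
    for (int k = 0; k < 8; ++k) {
      const int ni = pi + DI8[k], nj = pj + DJ8[k];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      const int q = ni + nj * H;
      if (lab[q] == 0) {
        FloodEntry e;
        e.level = rec[q]; e.order = counter++; e.pixel = q; e.label = lab[p];
        pq.push(e);
      }
    }
  }
  while (!pq.empty()) {
    const FloodEntry e = pq.top();
    pq.pop();
    if (lab[e.pixel] != 0) continue;
    lab[e.pixel] = e.label;
    const int pi = e.pixel % H, pj = e.pixel / H;
    for (int k = 0; k < 8; ++k) {
      const int ni = pi + DI8[k], nj = pj + DJ8[k];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      const int q = ni + nj * H;
      if (lab[q] == 0) {
        FloodEntry f;
        f.level = rec[q]; f.order = counter++; f.pixel = q; f.label = e.label;
        pq.push(f);
      }
    }
  }
  return lab;
}
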