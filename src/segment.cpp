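// Connected-component labelling (8-connectivity), interior hole filling and
// outer-boundary perimeter estimation by Moore tracing with
// Vossepoel-Smeulders chain weights. Coordinates follow the package
// convention: 0-based, x = column, y = row, pixel centers at integers.
#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <queue>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::queue<std::pair<int, int>> q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push({i, j});
      while (!q.empty()) {
        auto [ci, cj] = q.front();
        q.pop();
        for (int d = 0; d < 8; ++d) {
          int ni = ci + di[d], nj = cj + dj[d];
          if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            q.push({ni, nj});
          }
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Convex-hull perimeter of a cluster's pixel centers (Andrew's monotone
// chain over the per-row horizontal extremes). Robust against the
// noise-ragged threshold boundaries of defocused beads, which inflate
// chain-code perimeter estimates; beads and the elongated distractors are
// convex, so the hull length estimates their true outline well.
struct Pt { double x, y; };
static double cross(const Pt& o, const Pt& a, const Pt& b) {
  return (a.x - o.x) * (b.y - o.y) - (a.y - o.y) * (b.x - o.x);
}

static double hull_perimeter(std::vector<Pt>& pts) {
  size_t n = pts.size();
  if (n == 1) return 0.0;
  std::sort(pts.begin(), pts.end(), [](const Pt& a, const Pt& b) {
    return a.x < b.x || (a.x == b.x && a.y < b.y);
  });
  std::vector<Pt> h(2 * n);
  size_t k = 0;
  for (size_t i = 0; i < n; ++i) {
    while (k >= 2 && cross(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  size_t lower = k + 1;
  for (size_t i = n - 1; i-- > 0;) {
    while (k >= lower && cross(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  double p = 0;
  for (size_t i = 1; i < k; ++i)
    p += std::hypot(h[i].x - h[i - 1].x, h[i].y - h[i - 1].y);
  return p;
}

// filled cluster grid within its bounding box: background cells
// (4-connectivity) not reachable from the bbox border are interior holes.
// Returns the hole area and, via `filled`, the hole-filled binary grid
// (column-major, h x w).
static double fill_cluster(const IntegerMatrix& lab, int id, int y0, int y1,
                           int x0, int x1, std::vector<char>& filled) {
  int h = y1 - y0 + 1, w = x1 - x0 + 1;
  std::vector<char> state((size_t)h * w, 0); // 0 bg, 1 fg, 2 reached
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      if (lab(y0 + i, x0 + j) == id) state[(size_t)j * h + i] = 1;
  std::queue<std::pair<int, int>> q;
  auto push = [&](int i, int j) {
    char& s = state[(size_t)j * h + i];
    if (s == 0) { s = 2; q.push({i, j}); }
  };
  for (int j = 0; j < w; ++j) { push(0, j); push(h - 1, j); }
  for (int i = 0; i < h; ++i) { push(i, 0); push(i, w - 1); }
  while (!q.empty()) {
    auto [i, j] = q.front();
    q.pop();
    if (i > 0) push(i - 1, j);
    if (i < h - 1) push(i + 1, j);
    if (j > 0) push(i, j - 1);
    if (j < w - 1) push(i, j + 1);
  }
  double holes = 0;
  filled.assign((size_t)h * w, 0);
  for (size_t s = 0; s < state.size(); ++s) {
    if (state[s] != 2) {
      filled[s] = 1;
      if (state[s] == 0) holes += 1;
    }
  }
  return holes;
}

// one pass of 3x3 majority smoothing (count includes the center; keep when
// >= 5 of 9 are set; outside the grid counts as background)
static void majority_smooth(const std::vector<char>& in, int h, int w,
                            std::vector<char>& out) {
  out.assign(in.size(), 0);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      int cnt = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= w) continue;
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di;
          if (ii < 0 || ii >= h) continue;
          cnt += in[(size_t)jj * h + ii];
        }
      }
      if (cnt >= 5) out[(size_t)j * h + i] = 1;
    }
  }
}

// [[Rcpp::export(name = ".cluster_stats_cpp")]]
DataFrame cluster_stats_cpp(const IntegerMatrix& lab, int n_labels,
                            double min_trace_area = 0.0) {
  int nr = lab.nrow(), nc = lab.ncol();
  NumericVector area(n_labels), cx(n_labels), cy(n_labels), perim(n_labels);
  IntegerVector xmin(n_labels, nc), xmax(n_labels, -1), ymin(n_labels, nr),
      ymax(n_labels, -1);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int id = lab(i, j);
      if (id == 0) continue;
      int k = id - 1;
      area[k] += 1;
      cx[k] += j;
      cy[k] += i;
      if (j < xmin[k]) xmin[k] = j;
      if (j > xmax[k]) xmax[k] = j;
      if (i < ymin[k]) ymin[k] = i;
      if (i > ymax[k]) ymax[k] = i;
    }
  }
  for (int k = 0; k < n_labels; ++k) {
    cx[k] /= area[k];
    cy[k] /= area[k];
    if (area[k] < min_trace_area) {
      perim[k] = NA_REAL;
      continue;
    }
    // bright bead centers rise above the dark-pixel threshold and leave an
    // interior hole in the mask; fill it so area matches the physical bead
    std::vector<char> filled, smooth;
    int h = ymax[k] - ymin[k] + 1, w = xmax[k] - xmin[k] + 1;
    area[k] += fill_cluster(lab, k + 1, ymin[k], ymax[k], xmin[k], xmax[k],
                            filled);
    // the perimeter estimator works on a majority-smoothed copy so that
    // single-pixel noise spikes on the threshold boundary do not stretch
    // the hull; the stored mask and the area are untouched
    majority_smooth(filled, h, w, smooth);
    bool any = false;
    for (auto s : smooth) if (s) { any = true; break; }
    const std::vector<char>& grid = any ? smooth : filled;
    std::vector<Pt> pts;
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i)
        if (grid[(size_t)j * h + i])
          pts.push_back({(double)(xmin[k] + j), (double)(ymin[k] + i)});
    // hull through pixel centers sits half a pixel inside the true outline
    perim[k] = hull_perimeter(pts) + M_PI;
  }
  return DataFrame::create(
      _["label"] = seq_len(n_labels), _["area"] = area, _["x"] = cx,
      _["y"] = cy, _["perimeter"] = perim, _["xmin"] = xmin, _["xmax"] = xmax,
      _["ymin"] = ymin, _["ymax"] = ymax);
}
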