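#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Low-level raster primitives for nuclear segmentation. Matrices are
// column-major (R layout); a pixel (i, j) has linear index i + j * nrow.

// ---- connected-component labelling -----------------------------------

// Label foreground pixels of a binary mask with consecutive integers in
// raster-scan order of first encounter (deterministic).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nnb; ++k) {
          int qi = pi + di8[k], qj = pj + dj8[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// ---- exact Euclidean distance transform ------------------------------

// One-dimensional squared distance transform (lower envelope of
// parabolas, Felzenszwalb & Huttenlocher 2004).
// Large finite sentinel: true infinity breaks the parabola-intersection
// arithmetic (INF - INF = NaN).
static const double DT_BIG = 1e15;

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance from every pixel to the nearest FALSE pixel.
// Pixels of an all-TRUE mask get distance Inf.
// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix d2(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // columns
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? DT_BIG : 0.0;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) d2(i, j) = d[i];
  }
  // rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = d2(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) d2(i, j) = d[j];
  }
  NumericMatrix out(nr, nc);
  for (int p = 0; p < nr * nc; ++p)
    out[p] = (d2[p] >= DT_BIG / 2) ? R_PosInf : std::sqrt(d2[p]);
  return out;
}

// ---- marker-based watershed ------------------------------------------

struct WsNode {
  double prio;   // flood from high priority downwards
  long order;    // FIFO tie-break for determinism
  int idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.prio != b.prio) return a.prio < b.prio; // max-heap on priority
    return a.order > b.order;                     // earlier push wins
  }
};

// Grow marker labels over the mask in order of decreasing priority
// (classically: priority = distance transform, so basins flood outward
// from the ridge tops of each nucleus).
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& priority,
                            const IntegerMatrix& markers,
                            const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (priority.nrow() != nr || markers.nrow() != nr ||
      priority.ncol() != nc || markers.ncol() != nc)
    stop("priority, markers and mask must share dimensions");
  IntegerMatrix lab = clone(markers);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long counter = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0 && mask(i, j))
        pq.push(WsNode{priority(i, j), counter++, i + j * nr});
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int pi = nd.idx % nr, pj = nd.idx / nr;
    int l = lab(pi, pj);
    for (int k = 0; k < 8; ++k) {
      int qi = pi + di[k], qj = pj + dj[k];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      if (mask(qi, qj) && lab(qi, qj) == 0) {
        lab(qi, qj) = l;
        pq.push(WsNode{priority(qi, qj), counter++, qi + qj * nr});
      }
    }
  }
  return lab;
}

// ---- regional maxima --------------------------------------------------

// TRUE where img attains the maximum of its (2r+1)x(2r+1) Chebyshev
// neighbourhood and exceeds min_value. Plateaus yield multiple TRUEs;
// callers collapse them with cpp_label_components.
// [[Rcpp::export]]
LogicalMatrix cpp_local_maxima(const NumericMatrix& img, int radius,
                               double min_value) {
  const int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = img(i, j);
      if (v < min_value) continue;
      bool is_max = true;
      for (int dj = -radius; dj <= radius && is_max; ++dj) {
        int qj = j + dj;
        if (qj < 0 || qj >= nc) continue;
        for (int di = -radius; di <= radius; ++di) {
          int qi = i + di;
          if (qi < 0 || qi >= nr || (di == 0 && dj == 0)) continue;
          if (img(qi, qj) > v) { is_max = false; break; }
        }
      }
      out(i, j) = is_max;
    }
  }
  return out;
}
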