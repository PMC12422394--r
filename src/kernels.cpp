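// Low-level image kernels shared by the segmentation and vasculature stages.
// All 3D arrays use R column-major layout with dim = (n1, n2, n3) and linear
// index i1 + n1*(i2 + n2*i3).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int lidx(int i, int j, int k, int n1, int n2) {
  return i + n1 * (j + n2 * k);
}

// [[Rcpp::export]]
NumericMatrix median_filter2(NumericMatrix img, int k) {
  if (k < 1 || k % 2 == 0) stop("median filter size must be a positive odd integer");
  int nr = img.nrow(), nc = img.ncol(), h = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)k * k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -h; dj <= h; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nc - 1); // edge-replicate
        for (int di = -h; di <= h; ++di) {
          int ii = std::min(std::max(i + di, 0), nr - 1);
          buf.push_back(img(ii, jj));
        }
      }
      size_t m = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      out(i, j) = buf[m];
    }
  }
  return out;
}

// 26- or 6-connected component labelling of a 3D logical mask.
// Returns integer labels, 0 = background, components numbered from 1 in
// first-encounter (scan) order so labels are deterministic.
// [[Rcpp::export]]
IntegerVector label_components3(LogicalVector mask, IntegerVector dims, int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  if ((R_xlen_t)n1 * n2 * n3 != mask.size()) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  std::vector<std::array<int,3>> nb;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({di, dj, dk});
      }

  IntegerVector labels(mask.size(), 0);
  std::vector<int> stack;
  int next = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int v = lidx(i, j, k, n1, n2);
        if (!mask[v] || labels[v] != 0) continue;
        labels[v] = ++next;
        stack.clear();
        stack.push_back(v);
        while (!stack.empty()) {
          int cur = stack.back(); stack.pop_back();
          int ck = cur / (n1 * n2), rem = cur % (n1 * n2);
          int cj = rem / n1, ci = rem % n1;
          for (auto &d : nb) {
            int ii = ci + d[0], jj = cj + d[1], kk = ck + d[2];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
            int w = lidx(ii, jj, kk, n1, n2);
            if (mask[w] && labels[w] == 0) { labels[w] = next; stack.push_back(w); }
          }
        }
      }
  return labels;
}

// Felzenszwalb-Huttenlocher 1D squared distance transform with sample spacing w.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  double w2 = w * w;
  int q = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int p = 1; p < n; ++p) {
    double s;
    while (true) {
      int vq = v[q];
      s = ((f[p] + w2 * p * p) - (f[vq] + w2 * vq * vq)) / (2.0 * w2 * (p - vq));
      if (s > z[q]) break;
      --q;
    }
    ++q;
    v[q] = p; z[q] = s; z[q + 1] = std::numeric_limits<double>::infinity();
  }
  q = 0;
  for (int p = 0; p < n; ++p) {
    while (z[q + 1] < p) ++q;
    double dp = (double)(p - v[q]);
    d[p] = w2 * dp * dp + f[v[q]];
  }
}

// Anisotropic Euclidean distance transform: for every voxel, the distance (in
// physical units given by `spacing`) to the nearest background voxel center.
// Background voxels get 0. If the mask has no background the distance is Inf.
// [[Rcpp::export]]
NumericVector edt3(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  if (dims.size() != 3 || spacing.size() != 3) stop("dims and spacing must have length 3");
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (n != mask.size()) stop("mask length does not match dims");
  // large finite sentinel instead of Inf: keeps the parabola intersections
  // finite when a scan line contains no background sample
  const double INF = 1e30;
  std::vector<double> d(n);
  for (R_xlen_t v = 0; v < n; ++v) d[v] = mask[v] ? INF : 0.0;

  std::vector<double> f, g;
  // axis 1
  f.resize(n1); g.resize(n1);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      bool any = false;
      for (int i = 0; i < n1; ++i) { f[i] = d[lidx(i, j, k, n1, n2)]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, g, n1, spacing[0]);
      for (int i = 0; i < n1; ++i) d[lidx(i, j, k, n1, n2)] = g[i];
    }
  // axis 2
  f.resize(n2); g.resize(n2);
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      bool any = false;
      for (int j = 0; j < n2; ++j) { f[j] = d[lidx(i, j, k, n1, n2)]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f, g, n2, spacing[1]);
      for (int j = 0; j < n2; ++j) d[lidx(i, j, k, n1, n2)] = g[j];
    }
  // axis 3
  f.resize(n3); g.resize(n3);
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      bool any = false;
      for (int k = 0; k < n3; ++k) { f[k] = d[lidx(i, j, k, n1, n2)]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f, g, n3, spacing[2]);
      for (int k = 0; k < n3; ++k) d[lidx(i, j, k, n1, n2)] = g[k];
    }

  NumericVector out(n);
  for (R_xlen_t v = 0; v < n; ++v) out[v] = std::sqrt(d[v]);
  return out;
}

// ---- 3D curve thinning -----------------------------------------------------
// Topology-preserving skeletonization by iterative removal of simple border
// points (Malandain-Bertrand simple-point characterization, six directional
// subiterations, curve endpoints preserved).

// occupancy of the 3x3x3 neighborhood; local index di+1 + 3*(dj+1) + 9*(dk+1)
static inline void fill_nbhd(const std::vector<char> &msk, int i, int j, int k,
                             int n1, int n2, int n3, bool nb[27]) {
  int t = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di, ++t) {
        int ii = i + di, jj = j + dj, kk = k + dk;
        nb[t] = (ii >= 0 && jj >= 0 && kk >= 0 && ii < n1 && jj < n2 && kk < n3)
                  ? (msk[lidx(ii, jj, kk, n1, n2)] != 0) : false;
      }
}

static inline void loc_coord(int t, int &x, int &y, int &z) {
  x = t % 3 - 1; y = (t / 3) % 3 - 1; z = t / 9 - 1;
}

// number of 26-connected components of object voxels within N26 (center excluded)
static int n26_object_components(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    std::vector<int> st{s};
    seen[s] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cx, cy, cz; loc_coord(c, cx, cy, cz);
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || seen[t] || !nb[t]) continue;
        int tx, ty, tz; loc_coord(t, tx, ty, tz);
        if (std::abs(tx - cx) <= 1 && std::abs(ty - cy) <= 1 && std::abs(tz - cz) <= 1)
          { seen[t] = true; st.push_back(t); }
      }
    }
  }
  return comps;
}

// number of 6-connected components of background voxels within N18 that are
// 6-adjacent to the center
static int n6_background_components(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || nb[s] || seen[s]) continue;
    int sx, sy, sz; loc_coord(s, sx, sy, sz);
    if (std::abs(sx) + std::abs(sy) + std::abs(sz) != 1) continue; // seed at 6-neighbors
    ++comps;
    std::vector<int> st{s};
    seen[s] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cx, cy, cz; loc_coord(c, cx, cy, cz);
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || seen[t] || nb[t]) continue;
        int tx, ty, tz; loc_coord(t, tx, ty, tz);
        if (std::abs(tx) + std::abs(ty) + std::abs(tz) > 2) continue; // stay in N18
        if (std::abs(tx - cx) + std::abs(ty - cy) + std::abs(tz - cz) == 1)
          { seen[t] = true; st.push_back(t); }
      }
    }
  }
  return comps;
}

static inline int count_object_neighbors(const bool nb[27]) {
  int c = 0;
  for (int t = 0; t < 27; ++t) if (t != 13 && nb[t]) ++c;
  return c;
}

static inline bool is_simple(const bool nb[27]) {
  return n26_object_components(nb) == 1 && n6_background_components(nb) == 1;
}

// [[Rcpp::export]]
LogicalVector skeletonize3(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (n != mask.size()) stop("mask length does not match dims");
  std::vector<char> m(n);
  for (R_xlen_t v = 0; v < n; ++v) m[v] = mask[v] ? 1 : 0;

  const int dir[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  bool nb[27];
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int k = 0; k < n3; ++k)
        for (int j = 0; j < n2; ++j)
          for (int i = 0; i < n1; ++i) {
            int v = lidx(i, j, k, n1, n2);
            if (!m[v]) continue;
            int ii = i + dir[d][0], jj = j + dir[d][1], kk = k + dir[d][2];
            bool border = (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
                            ? true : (m[lidx(ii, jj, kk, n1, n2)] == 0);
            if (!border) continue;
            fill_nbhd(m, i, j, k, n1, n2, n3, nb);
            if (count_object_neighbors(nb) <= 1) continue; // curve endpoint
            if (is_simple(nb)) cand.push_back(v);
          }
      // sequential re-check so deletions within a subiteration stay topology-safe
      for (int v : cand) {
        int kk = v / (n1 * n2), rem = v % (n1 * n2);
        int jj = rem / n1, ii = rem % n1;
        fill_nbhd(m, ii, jj, kk, n1, n2, n3, nb);
        if (count_object_neighbors(nb) <= 1) continue;
        if (is_simple(nb)) { m[v] = 0; changed = true; }
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t v = 0; v < n; ++v) out[v] = m[v] != 0;
  return out;
}
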