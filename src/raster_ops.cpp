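#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 4-neighbor boundary mask: a pixel is a boundary pixel if any 4-neighbor
// inside the frame carries a different label (marks both sides, so internal
// boundaries are 2 px thick; the image border itself is not a boundary).
// [[Rcpp::export]]
LogicalMatrix cpp_boundary_mask(IntegerMatrix lab) {
  int nr = lab.nrow(), nc = lab.ncol();
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int v = lab(r, c);
      bool b = false;
      if (r > 0      && lab(r - 1, c) != v) b = true;
      else if (r < nr - 1 && lab(r + 1, c) != v) b = true;
      else if (c > 0      && lab(r, c - 1) != v) b = true;
      else if (c < nc - 1 && lab(r, c + 1) != v) b = true;
      out(r, c) = b;
    }
  }
  return out;
}

// Multi-source BFS fill: pixels equal to `hole` take the label of the
// nearest (4-neighbor BFS metric) non-hole pixel. Deterministic: seeds
// are enqueued in column-major order and ties resolve by first
// arrival. Only non-hole pixels adjacent to a hole seed the wavefront
// (other seeds could never write anything).
// [[Rcpp::export]]
IntegerMatrix cpp_fill_nearest(IntegerMatrix lab, int hole) {
  int nr = lab.nrow(), nc = lab.ncol();
  IntegerMatrix out = clone(lab);
  std::queue<int> q;
  bool anyHole = false, anySeed = false;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (out(r, c) == hole) { anyHole = true; continue; }
      anySeed = true;
      bool adj =
        (r > 0      && out(r - 1, c) == hole) ||
        (r < nr - 1 && out(r + 1, c) == hole) ||
        (c > 0      && out(r, c - 1) == hole) ||
        (c < nc - 1 && out(r, c + 1) == hole);
      if (adj) q.push(c * nr + r);
    }
  }
  if (!anyHole || !anySeed) return out; // nothing to fill; caller handles
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int r = idx % nr, c = idx / nr;
    int v = out(r, c);
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (out(rr, cc) == hole) {
        out(rr, cc) = v;
        q.push(cc * nr + rr);
      }
    }
  }
  return out;
}

// Forward-warp an integer label raster by a per-pixel flow field
// (fx = displacement along columns/x, fy = along rows/y, in px, mapping
// frame t to t+1). Destination collisions keep the larger label
// (foreground occludes background deterministically); holes left by the
// warp are filled with the nearest surviving label.
// [[Rcpp::export]]
IntegerMatrix cpp_warp_labels(IntegerMatrix lab, NumericMatrix fx,
                              NumericMatrix fy) {
  int nr = lab.nrow(), nc = lab.ncol();
  IntegerMatrix dest(nr, nc);
  std::fill(dest.begin(), dest.end(), NA_INTEGER);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double dx = fx(r, c), dy = fy(r, c);
      if (NumericMatrix::is_na(dx) || NumericMatrix::is_na(dy))
        stop("NaN flow");
      int rr = r + (int)std::lround(dy);
      int cc = c + (int)std::lround(dx);
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int v = lab(r, c);
      int cur = dest(rr, cc);
      if (cur == NA_INTEGER || v > cur) dest(rr, cc) = v;
    }
  }
  return cpp_fill_nearest(dest, NA_INTEGER);
}

// Symmetric mean chamfer distance between two boundary-pixel sets, given
// their distance transforms; optional window restriction. Returns the
// mean of the defined one-sided terms, or 0 if neither side has
// boundary pixels (in the window).
// [[Rcpp::export]]
double cpp_chamfer(LogicalMatrix bmA, NumericMatrix distA,
                   LogicalMatrix bmB, NumericMatrix distB,
                   Nullable<LogicalMatrix> window = R_NilValue) {
  int n = bmA.size();
  bool hasWin = window.isNotNull();
  LogicalMatrix win;
  if (hasWin) win = window.get();
  double sA = 0, sB = 0;
  long nA = 0, nB = 0;
  for (int i = 0; i < n; ++i) {
    if (hasWin && !win[i]) continue;
    if (bmA[i]) { sA += distB[i]; ++nA; }
    if (bmB[i]) { sB += distA[i]; ++nB; }
  }
  if (nA == 0 && nB == 0) return 0.0;
  if (nA == 0) return sB / nB;
  if (nB == 0) return sA / nA;
  return 0.5 * (sA / nA + sB / nB);
}

// Pairwise overlap counts between two label rasters: inter[a, b] = number
// of pixels with labels (a, b), plus marginal label counts. Labels above
// the stated maxima are ignored (callers pass the true maxima).
// [[Rcpp::export]]
List cpp_overlap_counts(IntegerMatrix a, IntegerMatrix b, int maxA,
                        int maxB) {
  IntegerMatrix inter(maxA, maxB);
  IntegerVector na(maxA), nb(maxB);
  int n = a.size();
  for (int i = 0; i < n; ++i) {
    int va = a[i], vb = b[i];
    if (va >= 1 && va <= maxA) ++na[va - 1];
    if (vb >= 1 && vb <= maxB) ++nb[vb - 1];
    if (va >= 1 && va <= maxA && vb >= 1 && vb <= maxB)
      ++inter(va - 1, vb - 1);
  }
  return List::create(_["inter"] = inter, _["na"] = na, _["nb"] = nb);
}

#include <unordered_map>
#include <vector>

// Group identical label rasters: returns 1-based indices of group
// representatives (`uniq`) and, per raster, the group number (`map`).
// Hash buckets are verified by exact comparison, so the grouping is
// collision-safe.
// [[Rcpp::export]]
List cpp_dedup_index(List particles) {
  int n = particles.size();
  std::vector<IntegerMatrix> mats(n);
  std::vector<uint64_t> hs(n);
  for (int i = 0; i < n; ++i) {
    mats[i] = as<IntegerMatrix>(particles[i]);
    uint64_t h = 1469598103934665603ull;
    int m = mats[i].size();
    const int *p = mats[i].begin();
    // strided fingerprint; buckets are verified by exact comparison
    for (int j = 0; j < m; j += 4)
      h = (h ^ (uint64_t)(uint32_t)p[j]) * 1099511628211ull;
    h = (h ^ (uint64_t)(uint32_t)m) * 1099511628211ull;
    hs[i] = h;
  }
  std::unordered_map<uint64_t, std::vector<int> > buckets;
  IntegerVector map(n);
  std::vector<int> uniq;
  for (int i = 0; i < n; ++i) {
    std::vector<int> &bk = buckets[hs[i]];
    int grp = -1;
    for (size_t k = 0; k < bk.size(); ++k) {
      int j = uniq[bk[k]];
      if (mats[i].size() == mats[j].size() &&
          std::equal(mats[i].begin(), mats[i].end(), mats[j].begin())) {
        grp = bk[k]; break;
      }
    }
    if (grp < 0) {
      uniq.push_back(i);
      grp = (int)uniq.size() - 1;
      bk.push_back(grp);
    }
    map[i] = grp + 1;
  }
  IntegerVector u(uniq.size());
  for (size_t k = 0; k < uniq.size(); ++k) u[k] = uniq[k] + 1;
  return List::create(_["uniq"] = u, _["map"] = map);
}

// Renumber labels to 1..K in column-major first-occurrence order, so
// structurally identical rasters become bit-identical.
// [[Rcpp::export]]
IntegerMatrix cpp_canonical_labels(IntegerMatrix lab) {
  int n = lab.size();
  IntegerMatrix out(lab.nrow(), lab.ncol());
  std::unordered_map<int, int> remap;
  int next = 1;
  for (int i = 0; i < n; ++i) {
    int v = lab[i];
    std::unordered_map<int, int>::iterator it = remap.find(v);
    if (it == remap.end()) { remap[v] = next; out[i] = next; ++next; }
    else out[i] = it->second;
  }
  return out;
}

// Exact Euclidean distance transform (two-pass 1-D parabola method) to
// the nearest TRUE pixel of `mask`. Matches a reference exact EDT to
// floating-point precision; used in the per-frame likelihood loop.
static void edt_1d(const std::vector<double> &f, std::vector<double> &d,
                   int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -1e20; z[1] = 1e20;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = 1e20;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  const double INF = 1e20;
  // column pass
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? 0.0 : INF;
    edt_1d(f, d, nr);
    for (int r = 0; r < nr; ++r) out(r, c) = d[r];
  }
  // row pass
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = out(r, c);
    edt_1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = std::sqrt(d[c]);
  }
  return out;
}

// Canonicalize, paint the given segments (lists of 1-based pixel
// indices) with fresh labels, dissolve labels reduced below half their
// former extent into the nearest surviving label, and canonicalize
// again. One fused pass of the incorporation adjustment.
// [[Rcpp::export]]
IntegerMatrix cpp_paint_segments(IntegerMatrix p0, List segIdx) {
  // fast path: a single segment that is already an exact label of the
  // particle repaints to an identical (canonical) raster
  if (segIdx.size() == 1) {
    IntegerVector idx = segIdx[0];
    if (idx.size() > 0) {
      int v = p0[idx[0] - 1];
      bool same = true;
      for (int j = 1; j < idx.size(); ++j)
        if (p0[idx[j] - 1] != v) { same = false; break; }
      if (same) {
        int cnt = 0, n0 = p0.size();
        for (int i = 0; i < n0; ++i) if (p0[i] == v) ++cnt;
        if (cnt == idx.size()) return cpp_canonical_labels(p0);
      }
    }
  }
  IntegerMatrix p = cpp_canonical_labels(p0);
  int n = p.size();
  int K = 0;
  for (int i = 0; i < n; ++i) if (p[i] > K) K = p[i];
  std::vector<int> pre(K + 1, 0);
  for (int i = 0; i < n; ++i) ++pre[p[i]];
  int fresh = K;
  for (int s = 0; s < segIdx.size(); ++s) {
    IntegerVector idx = segIdx[s];
    ++fresh;
    for (int j = 0; j < idx.size(); ++j) p[idx[j] - 1] = fresh;
  }
  std::vector<int> post(K + 1, 0);
  for (int i = 0; i < n; ++i) if (p[i] <= K) ++post[p[i]];
  std::vector<char> gone(K + 1, 0);
  bool any = false;
  for (int l = 1; l <= K; ++l)
    if (pre[l] > 0 && post[l] * 2 < pre[l]) { gone[l] = 1; any = true; }
  if (any) {
    for (int i = 0; i < n; ++i)
      if (p[i] <= K && gone[p[i]]) p[i] = -1;
    p = cpp_fill_nearest(p, -1);
  }
  return cpp_canonical_labels(p);
}
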