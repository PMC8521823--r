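#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Connectivity convention: 8-connectivity for objects throughout,
// 4-neighbour background test for perimeter pixels (done in R).

// 8-connected component labelling; labels assigned in row-major scan
// order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& fg) {
  const int nr = fg.nrow(), nc = fg.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!fg(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int rr = cr + dr[k], cc2 = cc + dc[k];
          if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
          if (fg(rr, cc2) && lab(rr, cc2) == 0) {
            lab(rr, cc2) = next;
            stack.push_back(rr + cc2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

struct PqItem {
  double h;
  unsigned long order;
  int idx;
  int label;
};
struct PqCmp {
  bool operator()(const PqItem& a, const PqItem& b) const {
    if (a.h != b.h) return a.h > b.h;      // min-heap on height
    return a.order > b.order;              // FIFO tie-break
  }
};

// Seeded watershed by priority flood on `height` (basins grow uphill
// from seed minima), restricted to `mask`, 8-connected. Deterministic:
// ties in height resolve by insertion order.
// [[Rcpp::export]]
IntegerMatrix cpp_seeded_watershed(const NumericMatrix& height,
                                   const IntegerMatrix& seeds,
                                   const LogicalMatrix& mask) {
  const int nr = height.nrow(), nc = height.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::priority_queue<PqItem, std::vector<PqItem>, PqCmp> pq;
  unsigned long counter = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c)) {
        lab(r, c) = seeds(r, c);
        pq.push({height(r, c), counter++, r + c * nr, seeds(r, c)});
      }
  while (!pq.empty()) {
    PqItem it = pq.top();
    pq.pop();
    int cr = it.idx % nr, cc = it.idx / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = cr + dr[k], cc2 = cc + dc[k];
      if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
      if (!mask(rr, cc2) || lab(rr, cc2) != 0) continue;
      lab(rr, cc2) = it.label;
      pq.push({height(rr, cc2), counter++, rr + cc2 * nr, it.label});
    }
  }
  return lab;
}

// Exact Euclidean nearest-seed assignment within maxDist, ties to the
// lower seed label. Offsets are scanned in groups of equal squared
// distance so the reported seed is a true global minimiser.
// [[Rcpp::export]]
IntegerMatrix cpp_nearest_seed(const IntegerMatrix& seeds, double maxDist) {
  const int nr = seeds.nrow(), nc = seeds.ncol();
  IntegerMatrix lab(nr, nc);
  if (maxDist < 0) return lab;
  const int R = (int)std::floor(maxDist);
  const double maxD2 = maxDist * maxDist;
  // offsets sorted by squared distance
  std::vector<std::array<int, 3>> off;  // {d2, dr, dc}
  for (int dr = -R; dr <= R; ++dr)
    for (int dc = -R; dc <= R; ++dc) {
      int d2 = dr * dr + dc * dc;
      if ((double)d2 <= maxD2) off.push_back({d2, dr, dc});
    }
  std::sort(off.begin(), off.end());
  const int nOff = (int)off.size();
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (seeds(r, c) > 0) {
        lab(r, c) = seeds(r, c);
        continue;
      }
      int best = 0, i = 0;
      while (i < nOff) {
        int d2 = off[i][0];
        // scan the whole equal-distance group, keep lowest label
        for (; i < nOff && off[i][0] == d2; ++i) {
          int rr = r + off[i][1], cc = c + off[i][2];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          int s = seeds(rr, cc);
          if (s > 0 && (best == 0 || s < best)) best = s;
        }
        if (best > 0) break;
      }
      lab(r, c) = best;
    }
  }
  return lab;
}

// Pixel-set (boundary-to-boundary) neighbour relation: labels A,B are
// neighbours iff some pixel of A is within `dist` (Euclidean) of some
// pixel of B. Returns a symmetric logical adjacency matrix.
// [[Rcpp::export]]
LogicalMatrix cpp_neighbor_adjacency(const IntegerMatrix& labels,
                                     double dist, int nLabels) {
  const int nr = labels.nrow(), nc = labels.ncol();
  LogicalMatrix adj(nLabels, nLabels);
  if (nLabels == 0) return adj;
  const int R = (int)std::floor(dist);
  const double d2max = dist * dist;
  std::vector<std::pair<int, int>> off;
  for (int dr = -R; dr <= R; ++dr)
    for (int dc = -R; dc <= R; ++dc) {
      if (dr == 0 && dc == 0) continue;
      if ((double)(dr * dr + dc * dc) <= d2max) off.push_back({dr, dc});
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int L = labels(r, c);
      if (L <= 0) continue;
      for (size_t k = 0; k < off.size(); ++k) {
        int rr = r + off[k].first, cc = c + off[k].second;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int M = labels(rr, cc);
        if (M > 0 && M != L) {
          adj(L - 1, M - 1) = true;
          adj(M - 1, L - 1) = true;
        }
      }
    }
  return adj;
}
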