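#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fixed neighbour enumeration: E, SE, S, SW, W, NW, N, NE.
// Rows increase southwards, columns eastwards (top-left origin).
static const int DR[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const int DC[8] = {1, 1, 0, -1, -1, -1, 0, 1};

struct HeapCell {
  double key;
  int idx;   // row-major index; tie-break for bitwise reproducibility
};
struct HeapCellCmp {
  bool operator()(const HeapCell &a, const HeapCell &b) const {
    if (a.key != b.key) return a.key > b.key;
    return a.idx > b.idx;
  }
};

// Priority-flood pit filling. Border cells are seeds; each cell is raised
// to at least (spill elevation + eps) so the filled surface drains
// strictly to the border, which makes D8 routing acyclic.
// [[Rcpp::export]]
NumericMatrix fill_pits_cpp(NumericMatrix dem, double eps) {
  const int nr = dem.nrow(), nc = dem.ncol(), n = nr * nc;
  NumericMatrix out(nr, nc);
  std::vector<bool> closed(n, false);
  std::priority_queue<HeapCell, std::vector<HeapCell>, HeapCellCmp> pq;

  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (r == 0 || c == 0 || r == nr - 1 || c == nc - 1) {
        int i = r * nc + c;
        out(r, c) = dem(r, c);
        closed[i] = true;
        pq.push({dem(r, c), i});
      }

  while (!pq.empty()) {
    HeapCell top = pq.top();
    pq.pop();
    int r = top.idx / nc, c = top.idx % nc;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
      int j = rr * nc + cc;
      if (closed[j]) continue;
      closed[j] = true;
      double e = dem(rr, cc);
      double spill = out(r, c) + eps;
      out(rr, cc) = (e > spill) ? e : spill;
      pq.push({out(rr, cc), j});
    }
  }
  return out;
}

// D8 flow direction on a pit-filled DEM: each cell points to the
// neighbour maximising drop/distance (diagonals cost sqrt(2)*cellsize);
// ties broken by the fixed enumeration order above. 0 = sink.
// [[Rcpp::export]]
IntegerMatrix d8_flow_cpp(NumericMatrix dem, double cellsize) {
  const int nr = dem.nrow(), nc = dem.ncol();
  const double sq2 = std::sqrt(2.0);
  IntegerMatrix dir(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double best = 0.0;
      int bestk = 0;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
        double dist = (DR[k] != 0 && DC[k] != 0) ? sq2 * cellsize : cellsize;
        double slope = (dem(r, c) - dem(rr, cc)) / dist;
        if (slope > best) {
          best = slope;
          bestk = k + 1;
        }
      }
      dir(r, c) = bestk;
    }
  return dir;
}

// Flow accumulation (contributing area in cells, including the cell
// itself) by Kahn's topological order over the D8 graph. Errors on
// cycles so malformed direction grids are rejected rather than looping.
// [[Rcpp::export]]
NumericMatrix flow_accum_cpp(IntegerMatrix dir) {
  const int nr = dir.nrow(), nc = dir.ncol(), n = nr * nc;
  NumericMatrix acc(nr, nc);
  std::vector<int> indeg(n, 0), order;
  order.reserve(n);
  std::fill(acc.begin(), acc.end(), 1.0);

  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      int d = dir(r, c);
      if (d > 0) indeg[(r + DR[d - 1]) * nc + (c + DC[d - 1])]++;
    }
  for (int i = 0; i < n; ++i)
    if (indeg[i] == 0) order.push_back(i);
  for (size_t h = 0; h < order.size(); ++h) {
    int i = order[h];
    int r = i / nc, c = i % nc, d = dir(r, c);
    if (d > 0) {
      int j = (r + DR[d - 1]) * nc + (c + DC[d - 1]);
      acc(r + DR[d - 1], c + DC[d - 1]) += acc(r, c);
      if (--indeg[j] == 0) order.push_back(j);
    }
  }
  if ((int)order.size() != n)
    stop("flow direction grid contains a cycle");
  return acc;
}

// Strahler stream ordering: cells with accumulation >= threshold are
// stream cells; a stream cell with no stream inflows is order 1, a
// junction where the maximal inflow order occurs at least twice
// increments it, otherwise the maximum passes through.
// [[Rcpp::export]]
IntegerMatrix strahler_cpp(IntegerMatrix dir, NumericMatrix acc,
                           double threshold) {
  const int nr = dir.nrow(), nc = dir.ncol(), n = nr * nc;
  IntegerMatrix ord(nr, nc);
  std::vector<int> indeg(n, 0), topo;
  topo.reserve(n);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      int d = dir(r, c);
      if (d > 0) indeg[(r + DR[d - 1]) * nc + (c + DC[d - 1])]++;
    }
  for (int i = 0; i < n; ++i)
    if (indeg[i] == 0) topo.push_back(i);
  for (size_t h = 0; h < topo.size(); ++h) {
    int i = topo[h];
    int r = i / nc, c = i % nc, d = dir(r, c);
    if (acc(r, c) >= threshold) {
      // gather stream inflows
      int maxo = 0, nmax = 0;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
        int du = dir(rr, cc);
        if (du > 0 && rr + DR[du - 1] == r && cc + DC[du - 1] == c) {
          int o = ord(rr, cc);
          if (o > 0) {
            if (o > maxo) { maxo = o; nmax = 1; }
            else if (o == maxo) nmax++;
          }
        }
      }
      ord(r, c) = (maxo == 0) ? 1 : (nmax >= 2 ? maxo + 1 : maxo);
    }
    if (d > 0) {
      int j = (r + DR[d - 1]) * nc + (c + DC[d - 1]);
      if (--indeg[j] == 0) topo.push_back(j);
    }
  }
  if ((int)topo.size() != n)
    stop("flow direction grid contains a cycle");
  return ord;
}

// Multi-source cost distance (Dijkstra) over an 8-connected grid.
// pace is minutes per metre; non-finite pace marks a barrier cell.
// Edge cost between neighbours a,b = dist(a,b) * (pace_a + pace_b) / 2
// with dist = cellsize (cardinal) or cellsize*sqrt(2) (diagonal).
// sources are 0-based row-major indices. Unreachable cells stay +Inf.
// [[Rcpp::export]]
NumericMatrix cost_distance_cpp(NumericMatrix pace, IntegerVector sources,
                                double cellsize) {
  const int nr = pace.nrow(), nc = pace.ncol(), n = nr * nc;
  const double sq2 = std::sqrt(2.0);
  NumericMatrix tt(nr, nc);
  std::fill(tt.begin(), tt.end(), R_PosInf);
  std::vector<bool> done(n, false);
  std::priority_queue<HeapCell, std::vector<HeapCell>, HeapCellCmp> pq;

  for (int s = 0; s < sources.size(); ++s) {
    int i = sources[s];
    if (i < 0 || i >= n) stop("source index out of range");
    int r = i / nc, c = i % nc;
    if (!R_FINITE(pace(r, c))) stop("source lies on a barrier cell");
    tt(r, c) = 0.0;
    pq.push({0.0, i});
  }
  if (sources.size() == 0) stop("no sources supplied");

  while (!pq.empty()) {
    HeapCell top = pq.top();
    pq.pop();
    int i = top.idx;
    if (done[i]) continue;
    done[i] = true;
    int r = i / nc, c = i % nc;
    double pr = pace(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
      double pn = pace(rr, cc);
      if (!R_FINITE(pn)) continue;
      double dist = (DR[k] != 0 && DC[k] != 0) ? sq2 * cellsize : cellsize;
      double cand = top.key + dist * 0.5 * (pr + pn);
      int j = rr * nc + cc;
      if (cand < tt(rr, cc)) {
        tt(rr, cc) = cand;
        pq.push({cand, j});
      }
    }
  }
  return tt;
}
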