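// 3D morphological primitives on R arrays (column-major, dims = c(nr, nc, ns)).
// All functions take the mask as a logical vector plus its dims and return a
// flat vector; the R wrappers restore the dim attribute.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Grid {
  int nr, nc, ns;
  Grid(IntegerVector d) : nr(d[0]), nc(d[1]), ns(d[2]) {}
  inline int size() const { return nr * nc * ns; }
  inline int idx(int i, int j, int k) const { return i + nr * (j + nc * k); }
};

// Neighbourhood offsets as (di, dj, dk) triples.
std::vector<std::array<int, 3>> neighbourhood(int connectivity) {
  std::vector<std::array<int, 3>> nb;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({di, dj, dk});
      }
  return nb;
}

}  // namespace

// Connected-component labelling; labels are consecutive positive integers in
// order of first (column-major) appearance, background = 0.
// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  Grid g(dims);
  IntegerVector lab(g.size(), 0);
  std::vector<std::array<int, 3>> nb = neighbourhood(connectivity);
  std::vector<int> stack;
  int next = 0;
  for (int k = 0; k < g.ns; ++k)
    for (int j = 0; j < g.nc; ++j)
      for (int i = 0; i < g.nr; ++i) {
        int p = g.idx(i, j, k);
        if (!mask[p] || lab[p]) continue;
        ++next;
        lab[p] = next;
        stack.push_back(p);
        while (!stack.empty()) {
          int q = stack.back();
          stack.pop_back();
          int qi = q % g.nr, qj = (q / g.nr) % g.nc, qk = q / (g.nr * g.nc);
          for (size_t n = 0; n < nb.size(); ++n) {
            int ii = qi + nb[n][0], jj = qj + nb[n][1], kk = qk + nb[n][2];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= g.nr || jj >= g.nc ||
                kk >= g.ns)
              continue;
            int r = g.idx(ii, jj, kk);
            if (mask[r] && !lab[r]) {
              lab[r] = next;
              stack.push_back(r);
            }
          }
        }
      }
  return lab;
}

// Erosion by the full 3x3x3 cube (in_plane: 3x3x1). A voxel survives iff all
// neighbours within the element are foreground; voxels on the array border
// are eroded (background outside).
// [[Rcpp::export(name = ".cpp_erode3d")]]
LogicalVector cpp_erode3d(LogicalVector mask, IntegerVector dims,
                          bool in_plane) {
  Grid g(dims);
  LogicalVector out(g.size(), false);
  int dk_max = in_plane ? 0 : 1;
  for (int k = 0; k < g.ns; ++k)
    for (int j = 0; j < g.nc; ++j)
      for (int i = 0; i < g.nr; ++i) {
        int p = g.idx(i, j, k);
        if (!mask[p]) continue;
        bool keep = true;
        for (int dk = -dk_max; dk <= dk_max && keep; ++dk)
          for (int dj = -1; dj <= 1 && keep; ++dj)
            for (int di = -1; di <= 1 && keep; ++di) {
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= g.nr || jj >= g.nc ||
                  kk >= g.ns) {
                keep = false;
              } else if (!mask[g.idx(ii, jj, kk)]) {
                keep = false;
              }
            }
        if (keep) out[p] = true;
      }
  return out;
}

// Multi-source BFS partition of a mask from labelled seeds, geodesic within
// the mask (26-connected steps). Deterministic: FIFO queue, seeds enqueued in
// column-major order. Unreached mask voxels keep label 0.
// [[Rcpp::export(name = ".cpp_geodesic_partition")]]
IntegerVector cpp_geodesic_partition(LogicalVector mask, IntegerVector seeds,
                                     IntegerVector dims) {
  Grid g(dims);
  IntegerVector lab(g.size(), 0);
  std::vector<std::array<int, 3>> nb = neighbourhood(26);
  std::queue<int> q;
  for (int p = 0; p < g.size(); ++p)
    if (mask[p] && seeds[p] > 0) {
      lab[p] = seeds[p];
      q.push(p);
    }
  while (!q.empty()) {
    int p = q.front();
    q.pop();
    int pi = p % g.nr, pj = (p / g.nr) % g.nc, pk = p / (g.nr * g.nc);
    for (size_t n = 0; n < nb.size(); ++n) {
      int ii = pi + nb[n][0], jj = pj + nb[n][1], kk = pk + nb[n][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= g.nr || jj >= g.nc ||
          kk >= g.ns)
        continue;
      int r = g.idx(ii, jj, kk);
      if (mask[r] && lab[r] == 0) {
        lab[r] = lab[p];
        q.push(r);
      }
    }
  }
  return lab;
}

// Chamfer distance transform: Euclidean-weighted two-pass (1, sqrt2, sqrt3).
// Distance from each foreground voxel to the nearest background voxel;
// background voxels get 0. Array borders count as background-adjacent via the
// implicit outside.
// [[Rcpp::export(name = ".cpp_chamfer3d")]]
NumericVector cpp_chamfer3d(LogicalVector mask, IntegerVector dims) {
  Grid g(dims);
  const double INF = 1e30;
  const double w1 = 1.0, w2 = std::sqrt(2.0), w3 = std::sqrt(3.0);
  NumericVector d(g.size());
  for (int p = 0; p < g.size(); ++p) d[p] = mask[p] ? INF : 0.0;
  auto weight = [&](int di, int dj, int dk) {
    int m = std::abs(di) + std::abs(dj) + std::abs(dk);
    return m == 1 ? w1 : (m == 2 ? w2 : w3);
  };
  auto relax = [&](int i, int j, int k, int di, int dj, int dk) {
    int ii = i + di, jj = j + dj, kk = k + dk;
    double dn;
    if (ii < 0 || jj < 0 || kk < 0 || ii >= g.nr || jj >= g.nc || kk >= g.ns)
      dn = 0.0;  // outside = background
    else
      dn = d[g.idx(ii, jj, kk)];
    double cand = dn + weight(di, dj, dk);
    int p = g.idx(i, j, k);
    if (cand < d[p]) d[p] = cand;
  };
  // Forward pass: neighbours already visited in column-major order.
  for (int k = 0; k < g.ns; ++k)
    for (int j = 0; j < g.nc; ++j)
      for (int i = 0; i < g.nr; ++i) {
        if (!mask[g.idx(i, j, k)]) continue;
        for (int dk = -1; dk <= 0; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (dk == 0 && (dj > 0 || (dj == 0 && di >= 0))) continue;
              relax(i, j, k, di, dj, dk);
            }
      }
  // Backward pass.
  for (int k = g.ns - 1; k >= 0; --k)
    for (int j = g.nc - 1; j >= 0; --j)
      for (int i = g.nr - 1; i >= 0; --i) {
        if (!mask[g.idx(i, j, k)]) continue;
        for (int dk = 0; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (dk == 0 && (dj < 0 || (dj == 0 && di <= 0))) continue;
              relax(i, j, k, di, dj, dk);
            }
      }
  return d;
}

// Seeded watershed by priority flooding: regions grow outward from the seeds
// in order of decreasing priority (for splitting, priority = distance
// transform, i.e. flooding the inverted distance map from its minima-side).
// Deterministic: ties broken by voxel index.
// [[Rcpp::export(name = ".cpp_watershed_seeded")]]
IntegerVector cpp_watershed_seeded(NumericVector priority, LogicalVector mask,
                                   IntegerVector seeds, IntegerVector dims) {
  Grid g(dims);
  IntegerVector lab(g.size(), 0);
  std::vector<std::array<int, 3>> nb = neighbourhood(26);
  // (priority, (-index, label)): -index gives deterministic tie-breaking
  std::priority_queue<std::pair<double, std::pair<int, int>>> pq;
  for (int p = 0; p < g.size(); ++p)
    if (mask[p] && seeds[p] > 0) {
      lab[p] = seeds[p];
      pq.push({priority[p], {-p, seeds[p]}});
    }
  while (!pq.empty()) {
    int p = -pq.top().second.first;
    pq.pop();
    int pi = p % g.nr, pj = (p / g.nr) % g.nc, pk = p / (g.nr * g.nc);
    for (size_t n = 0; n < nb.size(); ++n) {
      int ii = pi + nb[n][0], jj = pj + nb[n][1], kk = pk + nb[n][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= g.nr || jj >= g.nc ||
          kk >= g.ns)
        continue;
      int r = g.idx(ii, jj, kk);
      if (mask[r] && lab[r] == 0) {
        lab[r] = lab[p];
        pq.push({priority[r], {-r, lab[r]}});
      }
    }
  }
  return lab;
}

// Flood fill from a fixed set of seed voxels within a mask (hysteresis
// helper): returns the union of mask-connected components containing at
// least one seed.
// [[Rcpp::export(name = ".cpp_flood_from_seeds")]]
LogicalVector cpp_flood_from_seeds(LogicalVector mask, LogicalVector seed,
                                   IntegerVector dims, int connectivity) {
  Grid g(dims);
  LogicalVector out(g.size(), false);
  std::vector<std::array<int, 3>> nb = neighbourhood(connectivity);
  std::vector<int> stack;
  for (int p = 0; p < g.size(); ++p)
    if (mask[p] && seed[p] && !out[p]) {
      out[p] = true;
      stack.push_back(p);
      while (!stack.empty()) {
        int q = stack.back();
        stack.pop_back();
        int qi = q % g.nr, qj = (q / g.nr) % g.nc, qk = q / (g.nr * g.nc);
        for (size_t n = 0; n < nb.size(); ++n) {
          int ii = qi + nb[n][0], jj = qj + nb[n][1], kk = qk + nb[n][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= g.nr || jj >= g.nc ||
              kk >= g.ns)
            continue;
          int r = g.idx(ii, jj, kk);
          if (mask[r] && !out[r]) {
            out[r] = true;
            stack.push_back(r);
          }
        }
      }
    }
  return out;
}

// Greedy one-to-one assignment of candidate (parent, child) pairs already
// sorted by preference: returns TRUE for pairs accepted (both endpoints
// unused so far).
// [[Rcpp::export(name = ".cpp_greedy_assign")]]
LogicalVector cpp_greedy_assign(IntegerVector parent, IntegerVector child,
                                int n_parent, int n_child) {
  std::vector<char> up(n_parent + 1, 0), uc(n_child + 1, 0);
  int n = parent.size();
  LogicalVector take(n, false);
  for (int i = 0; i < n; ++i) {
    int p = parent[i], c = child[i];
    if (!up[p] && !uc[c]) {
      up[p] = 1; uc[c] = 1;
      take[i] = true;
    }
  }
  return take;
}
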