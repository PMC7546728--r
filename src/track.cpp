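// Vessel tracking support: geodesic BFS/Dijkstra over a binary component
// (26-connectivity, metric step lengths) and a 3-4-5 chamfer distance
// transform for diameter estimation.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Dijkstra over supra-threshold voxels from a seed; returns geodesic distance
// (mm), predecessor (1-based linear index, 0 = none/unreached) and component
// membership.
// [[Rcpp::export]]
List cpp_geodesic(LogicalVector mask, IntegerVector dims, int seed_index,
                  double voxel) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nv = static_cast<R_xlen_t>(nx) * ny * nz;
  NumericVector dist(nv, R_PosInf);
  IntegerVector prev(nv, 0);
  if (seed_index < 0 || seed_index >= nv || !mask[seed_index])
    stop("seed voxel is not inside the segmented component");
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  dist[seed_index] = 0.0;
  pq.push(Node(0.0, seed_index));
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    double d = nd.first;
    R_xlen_t q = nd.second;
    if (d > dist[q]) continue;
    int i = q % nx, j = (q / nx) % ny, k = q / (static_cast<R_xlen_t>(nx) * ny);
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          R_xlen_t p = ii + static_cast<R_xlen_t>(nx) *
                       (jj + static_cast<R_xlen_t>(ny) * kk);
          if (!mask[p]) continue;
          double step = voxel * std::sqrt(static_cast<double>(di * di +
                                                              dj * dj + dk * dk));
          if (d + step < dist[p]) {
            dist[p] = d + step;
            prev[p] = static_cast<double>(q) + 1;
            pq.push(Node(dist[p], p));
          }
        }
  }
  return List::create(_["dist"] = dist, _["prev"] = prev);
}

// Two-pass 3-4-5 chamfer distance to the background, scaled to mm.
// [[Rcpp::export]]
NumericVector cpp_chamfer(LogicalVector mask, IntegerVector dims,
                          double voxel) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nv = static_cast<R_xlen_t>(nx) * ny * nz;
  std::vector<double> d(nv);
  const double BIG = 1e30;
  for (R_xlen_t q = 0; q < nv; ++q) d[q] = mask[q] ? BIG : 0.0;
  const double w[3] = {3.0, 4.0, 5.0};
  // forward pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t q = i + static_cast<R_xlen_t>(nx) *
                     (j + static_cast<R_xlen_t>(ny) * k);
        if (d[q] == 0.0) continue;
        for (int dk = -1; dk <= 0; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (dk == 0 && (dj > 0 || (dj == 0 && di >= 0))) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              int m = std::abs(di) + std::abs(dj) + std::abs(dk);
              R_xlen_t p = ii + static_cast<R_xlen_t>(nx) *
                           (jj + static_cast<R_xlen_t>(ny) * kk);
              double cand = d[p] + w[m - 1];
              if (cand < d[q]) d[q] = cand;
            }
      }
  // backward pass
  for (int k = nz - 1; k >= 0; --k)
    for (int j = ny - 1; j >= 0; --j)
      for (int i = nx - 1; i >= 0; --i) {
        R_xlen_t q = i + static_cast<R_xlen_t>(nx) *
                     (j + static_cast<R_xlen_t>(ny) * k);
        if (d[q] == 0.0) continue;
        for (int dk = 0; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (dk == 0 && (dj < 0 || (dj == 0 && di <= 0))) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              int m = std::abs(di) + std::abs(dj) + std::abs(dk);
              R_xlen_t p = ii + static_cast<R_xlen_t>(nx) *
                           (jj + static_cast<R_xlen_t>(ny) * kk);
              double cand = d[p] + w[m - 1];
              if (cand < d[q]) d[q] = cand;
            }
      }
  NumericVector out(nv);
  for (R_xlen_t q = 0; q < nv; ++q)
    out[q] = d[q] >= BIG ? NA_REAL : d[q] * voxel / 3.0;
  return out;
}
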