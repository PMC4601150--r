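// Voxel-graph cores: competing fuzzy-connectedness propagation, exact
// anisotropic Euclidean distance transform, and multi-source geodesic
// Dijkstra with optional medialness weighting (used by the centerline tracer).
// All distances are in mm (spacing-aware); indices are 0-based linear offsets
// into column-major arrays of dimension (nx, ny, nz).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct FcEntry {
  double strength;   // path strength (max-min affinity), higher is better
  double dist;       // geodesic mm distance from the seed, tie-break (smaller wins)
  long   order;      // insertion order, final tie-break
  int    idx;
  int    label;
};

struct FcCompare {
  // priority_queue keeps the *largest* element on top under this "less-than"
  bool operator()(const FcEntry& a, const FcEntry& b) const {
    if (a.strength != b.strength) return a.strength < b.strength;
    if (a.dist != b.dist) return a.dist > b.dist;
    return a.order > b.order;
  }
};

// trapezoidal in-band membership: 0 at/below lt, linear ramp up to 1 at the
// contrast value ca, 1 on [ca, ut], 0 above ut (ut = +Inf for MRA)
inline double membership(double v, double lt, double ut, double ca) {
  if (!(v > lt)) return 0.0;
  if (v > ut) return 0.0;
  if (v >= ca) return 1.0;
  return (v - lt) / (ca - lt);
}

struct GeoEntry {
  double cost;
  int    idx;
};
struct GeoCompare {
  bool operator()(const GeoEntry& a, const GeoEntry& b) const {
    return a.cost > b.cost;
  }
};

} // namespace

// [[Rcpp::export]]
List fc_segment_cpp(NumericVector values, IntegerVector dims,
                    NumericVector spacing, IntegerVector seed_idx0,
                    IntegerVector seed_label, double lt, double ut, double ca) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;

  std::vector<double> strength(n, 0.0), dist(n, INF);
  std::vector<int> label(n, 0);
  std::vector<char> done(n, 0);

  // 6-neighbourhood: linear offsets and mm step lengths
  const int d_off[6] = {-1, +1, -nx, +nx, -nx * ny, +nx * ny};
  const double d_len[6] = {spacing[0], spacing[0], spacing[1],
                           spacing[1], spacing[2], spacing[2]};

  std::priority_queue<FcEntry, std::vector<FcEntry>, FcCompare> pq;
  long order = 0;
  for (int s = 0; s < seed_idx0.size(); ++s) {
    int i = seed_idx0[s];
    if (i < 0 || i >= n) stop("seed index out of range");
    if (membership(values[i], lt, ut, ca) <= 0.0)
      continue;  // out-of-band seeds contribute nothing
    pq.push({1.0, 0.0, order++, i, seed_label[s]});
  }
  if (pq.empty()) stop("all seeds lie outside the [LT, UT] intensity band");

  while (!pq.empty()) {
    FcEntry e = pq.top();
    pq.pop();
    if (done[e.idx]) continue;
    done[e.idx] = 1;
    strength[e.idx] = e.strength;
    dist[e.idx] = e.dist;
    label[e.idx] = e.label;

    const int x = e.idx % nx;
    const int y = (e.idx / nx) % ny;
    const int z = e.idx / (nx * ny);
    const double gi = membership(values[e.idx], lt, ut, ca);

    for (int k = 0; k < 6; ++k) {
      if ((k == 0 && x == 0) || (k == 1 && x == nx - 1) ||
          (k == 2 && y == 0) || (k == 3 && y == ny - 1) ||
          (k == 4 && z == 0) || (k == 5 && z == nz - 1))
        continue;
      const int j = e.idx + d_off[k];
      if (done[j]) continue;
      const double gj = membership(values[j], lt, ut, ca);
      const double aff = gi < gj ? gi : gj;
      if (aff <= 0.0) continue;
      const double ns = e.strength < aff ? e.strength : aff;
      const double nd = e.dist + d_len[k];
      if (ns > strength[j] || (ns == strength[j] && nd < dist[j])) {
        strength[j] = ns;
        dist[j] = nd;
        pq.push({ns, nd, order++, j, e.label});
      }
    }
  }

  IntegerVector out_label(n);
  NumericVector out_strength(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out_label[i] = done[i] ? label[i] : 0;
    out_strength[i] = done[i] ? strength[i] : 0.0;
  }
  out_label.attr("dim") = dims;
  out_strength.attr("dim") = dims;
  return List::create(Named("labels") = out_label,
                      Named("strength") = out_strength);
}

namespace {
// Felzenszwalb-Huttenlocher 1-D squared distance transform on physical
// coordinates x_i = i * s (lower envelope of parabolas).
void dt1d(std::vector<double>& f, std::vector<double>& d, double s,
          std::vector<int>& v, std::vector<double>& zb) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * s;
    while (true) {
      if (f[v[k]] == INF) {  // previous parabola is inert
        if (k == 0) { v[0] = q; zb[0] = -INF; zb[1] = INF; break; }
        --k;
        continue;
      }
      double xv = v[k] * s;
      double sct = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (sct <= zb[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        zb[k] = sct;
        zb[k + 1] = INF;
        break;
      }
    }
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (zb[kk + 1] < xq) ++kk;
    double xv = v[kk] * s;
    d[q] = (f[v[kk]] == INF) ? INF : (xq - xv) * (xq - xv) + f[v[kk]];
  }
}
} // namespace

// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      f.assign(d.begin() + base, d.begin() + base + nx);
      f.resize(nmax, INF);
      dt1d(f, g, spacing[0], v, zb);
      for (int x = 0; x < nx; ++x) d[base + x] = g[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = d[base + (R_xlen_t)y * nx];
      std::fill(f.begin() + ny, f.end(), INF);
      dt1d(f, g, spacing[1], v, zb);
      for (int y = 0; y < ny; ++y) d[base + (R_xlen_t)y * nx] = g[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = d[base + (R_xlen_t)z * nx * ny];
      std::fill(f.begin() + nz, f.end(), INF);
      dt1d(f, g, spacing[2], v, zb);
      for (int z = 0; z < nz; ++z) d[base + (R_xlen_t)z * nx * ny] = g[z];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (d[i] == INF) ? R_PosInf : std::sqrt(d[i]);
  out.attr("dim") = dims;
  return out;
}

// Multi-source Dijkstra over the TRUE voxels of `mask` with 26-connectivity.
// Edge cost = mm length * (w[a] + w[b]) / 2; pass an empty `weight` for plain
// geodesic mm distance. Returns per-voxel cost and predecessor (0-based linear
// index, -1 for sources/unreached).
// [[Rcpp::export]]
List geodesic_cpp(LogicalVector mask, IntegerVector dims,
                  NumericVector spacing, IntegerVector source_idx0,
                  NumericVector weight) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const bool weighted = weight.size() == n;

  std::vector<double> cost(n, INF);
  std::vector<int> pred(n, -1);
  std::vector<char> done(n, 0);

  // 26-neighbourhood offsets
  std::vector<int> d_off;
  std::vector<double> d_len;
  std::vector<int> d_dx, d_dy, d_dz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        d_off.push_back(dx + dy * nx + dz * nx * ny);
        d_dx.push_back(dx); d_dy.push_back(dy); d_dz.push_back(dz);
        double ex = dx * spacing[0], ey = dy * spacing[1], ez = dz * spacing[2];
        d_len.push_back(std::sqrt(ex * ex + ey * ey + ez * ez));
      }

  std::priority_queue<GeoEntry, std::vector<GeoEntry>, GeoCompare> pq;
  for (int s = 0; s < source_idx0.size(); ++s) {
    int i = source_idx0[s];
    if (i < 0 || i >= n) stop("source index out of range");
    if (!mask[i]) continue;
    if (cost[i] > 0.0) { cost[i] = 0.0; pq.push({0.0, i}); }
  }
  if (pq.empty()) stop("no source voxel lies inside the mask");

  while (!pq.empty()) {
    GeoEntry e = pq.top();
    pq.pop();
    if (done[e.idx]) continue;
    done[e.idx] = 1;
    const int x = e.idx % nx;
    const int y = (e.idx / nx) % ny;
    const int z = e.idx / (nx * ny);
    const double wi = weighted ? weight[e.idx] : 1.0;
    for (size_t k = 0; k < d_off.size(); ++k) {
      const int xx = x + d_dx[k], yy = y + d_dy[k], zz = z + d_dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      const int j = e.idx + d_off[k];
      if (done[j] || !mask[j]) continue;
      const double wj = weighted ? weight[j] : 1.0;
      const double nc = e.cost + d_len[k] * 0.5 * (wi + wj);
      if (nc < cost[j]) {
        cost[j] = nc;
        pred[j] = e.idx;
        pq.push({nc, j});
      }
    }
  }

  NumericVector out_cost(n);
  IntegerVector out_pred(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out_cost[i] = cost[i] == INF ? R_PosInf : cost[i];
    out_pred[i] = pred[i];
  }
  out_cost.attr("dim") = dims;
  return List::create(Named("cost") = out_cost, Named("pred") = out_pred);
}
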