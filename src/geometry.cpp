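// Geometric kernels: parity voxelization, point-in-mesh tests, exact
// point-to-triangle distance with a uniform-grid accelerator, marching
// tetrahedra isosurfacing, narrow-band signed distance sampling,
// Euclidean distance transforms, connected components and Taubin
// smoothing.  All coordinates are millimetres; grids are voxel-center
// sampled with half-open extents [origin + i*pitch, origin + (i+1)*pitch).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// deterministic tie-break shift for ray queries: keeps column centres off
// triangle edges/vertices without measurable geometric error
static const double RAY_EPS = 3.1e-7;
static const double RAY_EPS_Y = 1.7e-7;  // distinct from RAY_EPS so shifted
                                         // queries never sit on x=y diagonals

struct Vec3 {
  double x, y, z;
};

static inline Vec3 getv(const NumericMatrix& V, int i) {
  Vec3 p; p.x = V(i, 0); p.y = V(i, 1); p.z = V(i, 2); return p;
}

// ---- ray casting along +z -------------------------------------------------

// Does the vertical line through (qx,qy) cross triangle t?  If so set zhit.
static inline bool ray_z_hit(double qx, double qy,
                             const Vec3& a, const Vec3& b, const Vec3& c,
                             double& zhit) {
  const double d1x = b.x - a.x, d1y = b.y - a.y;
  const double d2x = c.x - a.x, d2y = c.y - a.y;
  const double det = d1x * d2y - d1y * d2x;
  if (std::fabs(det) < 1e-14) return false;  // vertical triangle: no parity
  const double px = qx - a.x, py = qy - a.y;
  const double u = (px * d2y - py * d2x) / det;
  const double v = (d1x * py - d1y * px) / det;
  if (u <= 0.0 || v <= 0.0 || u + v >= 1.0) return false;
  zhit = a.z + u * (b.z - a.z) + v * (c.z - a.z);
  return true;
}

// ---- voxelization by z-column parity --------------------------------------

// Occupancy at centres xs x ys x zs (x fastest).  A centre is occupied iff
// an odd number of surface crossings lie above it along +z.
// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           NumericVector xs, NumericVector ys,
                           NumericVector zs) {
  const int nx = xs.size(), ny = ys.size(), nz = zs.size();
  const int nf = F.nrow();
  std::vector<std::vector<double>> cross((size_t)nx * ny);
  const double x0 = xs[0], y0 = ys[0];
  const double dx = nx > 1 ? xs[1] - xs[0] : 1.0;
  const double dy = ny > 1 ? ys[1] - ys[0] : 1.0;
  for (int f = 0; f < nf; ++f) {
    Vec3 a = getv(V, F(f, 0)), b = getv(V, F(f, 1)), c = getv(V, F(f, 2));
    double xmin = std::min({a.x, b.x, c.x}), xmax = std::max({a.x, b.x, c.x});
    double ymin = std::min({a.y, b.y, c.y}), ymax = std::max({a.y, b.y, c.y});
    int i0 = (int)std::ceil((xmin - RAY_EPS - x0) / dx);
    int i1 = (int)std::floor((xmax - RAY_EPS - x0) / dx);
    int j0 = (int)std::ceil((ymin - RAY_EPS_Y - y0) / dy);
    int j1 = (int)std::floor((ymax - RAY_EPS_Y - y0) / dy);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    for (int j = j0; j <= j1; ++j) {
      const double qy = ys[j] + RAY_EPS_Y;
      for (int i = i0; i <= i1; ++i) {
        double zhit;
        if (ray_z_hit(xs[i] + RAY_EPS, qy, a, b, c, zhit))
          cross[(size_t)j * nx + i].push_back(zhit);
      }
    }
  }
  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      std::vector<double>& cz = cross[(size_t)j * nx + i];
      if (cz.empty()) continue;
      std::sort(cz.begin(), cz.end());
      // crossings above zs[k] = cz.size() - (first index with cz > z)
      int m = (int)cz.size();
      int ptr = 0;
      for (int k = 0; k < nz; ++k) {
        while (ptr < m && cz[ptr] <= zs[k]) ++ptr;
        if ((m - ptr) % 2 == 1)
          out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = true;
      }
    }
  }
  return out;
}

// Point-in-mesh parity test for arbitrary points (2D xy binning of faces).
// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix P, NumericMatrix V,
                                 IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < V.nrow(); ++i) {
    xmin = std::min(xmin, V(i, 0)); xmax = std::max(xmax, V(i, 0));
    ymin = std::min(ymin, V(i, 1)); ymax = std::max(ymax, V(i, 1));
  }
  int nb = std::max(1, (int)std::floor(std::sqrt((double)nf / 4.0)));
  nb = std::min(nb, 256);
  const double bx = (xmax - xmin) / nb + 1e-12, by = (ymax - ymin) / nb + 1e-12;
  std::vector<std::vector<int>> bins((size_t)nb * nb);
  for (int f = 0; f < nf; ++f) {
    Vec3 a = getv(V, F(f, 0)), b = getv(V, F(f, 1)), c = getv(V, F(f, 2));
    int i0 = std::max(0, (int)((std::min({a.x,b.x,c.x}) - xmin) / bx));
    int i1 = std::min(nb - 1, (int)((std::max({a.x,b.x,c.x}) - xmin) / bx));
    int j0 = std::max(0, (int)((std::min({a.y,b.y,c.y}) - ymin) / by));
    int j1 = std::min(nb - 1, (int)((std::max({a.y,b.y,c.y}) - ymin) / by));
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i)
        bins[(size_t)j * nb + i].push_back(f);
  }
  LogicalVector out(np);
  for (int p = 0; p < np; ++p) {
    const double qx = P(p, 0) + RAY_EPS, qy = P(p, 1) + RAY_EPS_Y, qz = P(p, 2);
    if (qx < xmin || qx > xmax || qy < ymin || qy > ymax) { out[p] = false; continue; }
    int bi = std::min(nb - 1, std::max(0, (int)((qx - xmin) / bx)));
    int bj = std::min(nb - 1, std::max(0, (int)((qy - ymin) / by)));
    int above = 0;
    for (int f : bins[(size_t)bj * nb + bi]) {
      Vec3 a = getv(V, F(f, 0)), b = getv(V, F(f, 1)), c = getv(V, F(f, 2));
      double zhit;
      if (ray_z_hit(qx, qy, a, b, c, zhit) && zhit > qz) ++above;
    }
    out[p] = (above % 2 == 1);
  }
  return out;
}

// ---- exact point-triangle distance (Ericson) ------------------------------

static inline double dot3(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 sub3(const Vec3& a, const Vec3& b) {
  Vec3 r; r.x = a.x - b.x; r.y = a.y - b.y; r.z = a.z - b.z; return r;
}

static double point_tri_dist2(const Vec3& p, const Vec3& a, const Vec3& b,
                              const Vec3& c) {
  Vec3 ab = sub3(b, a), ac = sub3(c, a), ap = sub3(p, a);
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0 && d2 <= 0) return dot3(ap, ap);
  Vec3 bp = sub3(p, b);
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0 && d4 <= d3) return dot3(bp, bp);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    Vec3 q; q.x = ap.x - v * ab.x; q.y = ap.y - v * ab.y; q.z = ap.z - v * ab.z;
    return dot3(q, q);
  }
  Vec3 cp = sub3(p, c);
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0 && d5 <= d6) return dot3(cp, cp);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    Vec3 q; q.x = ap.x - w * ac.x; q.y = ap.y - w * ac.y; q.z = ap.z - w * ac.z;
    return dot3(q, q);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    Vec3 bc = sub3(c, b);
    Vec3 q; q.x = bp.x - w * bc.x; q.y = bp.y - w * bc.y; q.z = bp.z - w * bc.z;
    return dot3(q, q);
  }
  double denom = va + vb + vc;
  double v = vb / denom, w = vc / denom;
  Vec3 q;
  q.x = ap.x - v * ab.x - w * ac.x;
  q.y = ap.y - v * ab.y - w * ac.y;
  q.z = ap.z - v * ab.z - w * ac.z;
  return dot3(q, q);
}

// uniform grid over triangles for nearest queries
struct TriGrid {
  double ox, oy, oz, cell;
  int nx, ny, nz;
  std::vector<std::vector<int>> cells;
  const NumericMatrix* V;
  const IntegerMatrix* F;
};

static void trigrid_build(TriGrid& g, const NumericMatrix& V,
                          const IntegerMatrix& F) {
  g.V = &V; g.F = &F;
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < V.nrow(); ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], V(i, k)); hi[k] = std::max(hi[k], V(i, k));
    }
  double diag = std::sqrt((hi[0]-lo[0])*(hi[0]-lo[0]) +
                          (hi[1]-lo[1])*(hi[1]-lo[1]) +
                          (hi[2]-lo[2])*(hi[2]-lo[2])) + 1e-9;
  // aim for ~8 triangles per occupied cell
  double target = std::cbrt((double)F.nrow() / 8.0 + 1.0);
  g.cell = std::max(diag / std::max(1.0, 4.0 * target), diag * 1e-3);
  g.ox = lo[0] - g.cell; g.oy = lo[1] - g.cell; g.oz = lo[2] - g.cell;
  g.nx = (int)std::ceil((hi[0] - g.ox) / g.cell) + 1;
  g.ny = (int)std::ceil((hi[1] - g.oy) / g.cell) + 1;
  g.nz = (int)std::ceil((hi[2] - g.oz) / g.cell) + 1;
  g.cells.assign((size_t)g.nx * g.ny * g.nz, {});
  for (int f = 0; f < F.nrow(); ++f) {
    Vec3 a = getv(V, F(f,0)), b = getv(V, F(f,1)), c = getv(V, F(f,2));
    int i0 = (int)((std::min({a.x,b.x,c.x}) - g.ox) / g.cell);
    int i1 = (int)((std::max({a.x,b.x,c.x}) - g.ox) / g.cell);
    int j0 = (int)((std::min({a.y,b.y,c.y}) - g.oy) / g.cell);
    int j1 = (int)((std::max({a.y,b.y,c.y}) - g.oy) / g.cell);
    int k0 = (int)((std::min({a.z,b.z,c.z}) - g.oz) / g.cell);
    int k1 = (int)((std::max({a.z,b.z,c.z}) - g.oz) / g.cell);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          g.cells[((size_t)k * g.ny + j) * g.nx + i].push_back(f);
  }
}

static double trigrid_nearest(const TriGrid& g, const Vec3& p) {
  const NumericMatrix& V = *g.V;
  const IntegerMatrix& F = *g.F;
  int ci = (int)((p.x - g.ox) / g.cell);
  int cj = (int)((p.y - g.oy) / g.cell);
  int ck = (int)((p.z - g.oz) / g.cell);
  ci = std::min(std::max(ci, 0), g.nx - 1);
  cj = std::min(std::max(cj, 0), g.ny - 1);
  ck = std::min(std::max(ck, 0), g.nz - 1);
  double best2 = R_PosInf;
  const int rmax = std::max({g.nx, g.ny, g.nz});
  for (int r = 0; r <= rmax; ++r) {
    // once a hit is found, shells beyond (r-1)*cell cannot improve
    if (best2 < R_PosInf) {
      double safe = (double)(r - 1) * g.cell;
      if (safe > 0 && safe * safe > best2) break;
    }
    bool any_cell = false;
    for (int k = ck - r; k <= ck + r; ++k) {
      if (k < 0 || k >= g.nz) continue;
      for (int j = cj - r; j <= cj + r; ++j) {
        if (j < 0 || j >= g.ny) continue;
        for (int i = ci - r; i <= ci + r; ++i) {
          if (i < 0 || i >= g.nx) continue;
          if (std::max({std::abs(i - ci), std::abs(j - cj), std::abs(k - ck)}) != r)
            continue;  // shell only
          any_cell = true;
          for (int f : g.cells[((size_t)k * g.ny + j) * g.nx + i]) {
            double d2 = point_tri_dist2(p, getv(V, F(f,0)), getv(V, F(f,1)),
                                        getv(V, F(f,2)));
            if (d2 < best2) best2 = d2;
          }
        }
      }
    }
    if (!any_cell && r > 0 && best2 < R_PosInf) break;
  }
  return std::sqrt(best2);
}

// Unsigned distance from each row of P to the surface of (V, F).
// [[Rcpp::export]]
NumericVector cpp_surface_distance(NumericMatrix P, NumericMatrix V,
                                   IntegerMatrix F) {
  TriGrid g;
  trigrid_build(g, V, F);
  const int np = P.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    Vec3 q; q.x = P(p,0); q.y = P(p,1); q.z = P(p,2);
    out[p] = trigrid_nearest(g, q);
  }
  return out;
}

// ---- narrow-band signed distance field ------------------------------------

// Signed distance (positive inside) sampled at voxel centres; exact within
// `band_cells` voxels of the surface, clamped to +/- band elsewhere.
// [[Rcpp::export]]
NumericVector cpp_sdf_grid(NumericMatrix V, IntegerMatrix F,
                           NumericVector xs, NumericVector ys,
                           NumericVector zs, double band, int band_cells) {
  const int nx = xs.size(), ny = ys.size(), nz = zs.size();
  LogicalVector occ = cpp_voxelize(V, F, xs, ys, zs);
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // mark voxels within band_cells (Chebyshev) of an occupancy transition
  std::vector<uint8_t> nearsurf(n, 0);
  auto at = [&](int i, int j, int k) -> R_xlen_t {
    return (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool o = occ[at(i,j,k)];
        bool edge = (i == 0 || j == 0 || k == 0 || i == nx-1 || j == ny-1 ||
                     k == nz-1) && o;
        if (!edge) {
          if (i > 0 && (bool)occ[at(i-1,j,k)] != o) edge = true;
          else if (i < nx-1 && (bool)occ[at(i+1,j,k)] != o) edge = true;
          else if (j > 0 && (bool)occ[at(i,j-1,k)] != o) edge = true;
          else if (j < ny-1 && (bool)occ[at(i,j+1,k)] != o) edge = true;
          else if (k > 0 && (bool)occ[at(i,j,k-1)] != o) edge = true;
          else if (k < nz-1 && (bool)occ[at(i,j,k+1)] != o) edge = true;
        }
        if (edge) {
          for (int dk = -band_cells; dk <= band_cells; ++dk)
            for (int dj = -band_cells; dj <= band_cells; ++dj)
              for (int di = -band_cells; di <= band_cells; ++di) {
                int ii = i + di, jj = j + dj, kk = k + dk;
                if (ii >= 0 && ii < nx && jj >= 0 && jj < ny &&
                    kk >= 0 && kk < nz)
                  nearsurf[at(ii,jj,kk)] = 1;
              }
        }
      }
  TriGrid g;
  trigrid_build(g, V, F);
  NumericVector out(n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = at(i,j,k);
        double s = occ[id] ? 1.0 : -1.0;
        if (nearsurf[id]) {
          Vec3 q; q.x = xs[i]; q.y = ys[j]; q.z = zs[k];
          out[id] = s * std::min(trigrid_nearest(g, q), band);
        } else {
          out[id] = s * band;
        }
      }
  return out;
}

// ---- marching tetrahedra --------------------------------------------------

struct EdgeKeyHash {
  size_t operator()(const uint64_t& k) const { return std::hash<uint64_t>()(k); }
};

// Contour `field` (values at voxel centres, dims nx*ny*nz, x fastest) at
// `iso`.  Inside = field > iso.  Returns watertight triangle mesh provided
// the boundary layer of the grid is entirely outside.
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims,
                       NumericVector xs, NumericVector ys, NumericVector zs,
                       double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto nid = [&](int i, int j, int k) -> uint64_t {
    return ((uint64_t)k * ny + j) * nx + i;
  };
  auto fval = [&](uint64_t id) { return field[(R_xlen_t)id]; };
  std::unordered_map<uint64_t, int, EdgeKeyHash> evert;
  std::vector<double> VX, VY, VZ;
  std::vector<int> FA, FB, FC;
  auto coord = [&](uint64_t id, double& x, double& y, double& z) {
    int i = (int)(id % nx);
    int j = (int)((id / nx) % ny);
    int k = (int)(id / ((uint64_t)nx * ny));
    x = xs[i]; y = ys[j]; z = zs[k];
  };
  auto edge_vertex = [&](uint64_t a, uint64_t b) -> int {
    uint64_t lo = std::min(a, b), hi = std::max(a, b);
    // grid ids < 2^31 by construction; pack the pair
    uint64_t key = (lo << 32) | (hi & 0xffffffffULL);
    auto it = evert.find(key);
    if (it != evert.end()) return it->second;
    double fa = fval(a), fb = fval(b);
    double t = (iso - fa) / (fb - fa);
    t = std::min(std::max(t, 1e-6), 1.0 - 1e-6);
    double ax, ay, az, bx, by, bz;
    coord(a, ax, ay, az); coord(b, bx, by, bz);
    VX.push_back(ax + t * (bx - ax));
    VY.push_back(ay + t * (by - ay));
    VZ.push_back(az + t * (bz - az));
    int idx = (int)VX.size() - 1;
    evert[key] = idx;
    return idx;
  };
  auto emit = [&](int v0, int v1, int v2, uint64_t inside_node) {
    // orient so the normal points away from the inside corner
    double ix, iy, iz;
    coord(inside_node, ix, iy, iz);
    double ux = VX[v1]-VX[v0], uy = VY[v1]-VY[v0], uz = VZ[v1]-VZ[v0];
    double wx = VX[v2]-VX[v0], wy = VY[v2]-VY[v0], wz = VZ[v2]-VZ[v0];
    double nxn = uy*wz - uz*wy, nyn = uz*wx - ux*wz, nzn = ux*wy - uy*wx;
    double cx = (VX[v0]+VX[v1]+VX[v2])/3.0 - ix;
    double cy = (VY[v0]+VY[v1]+VY[v2])/3.0 - iy;
    double cz = (VZ[v0]+VZ[v1]+VZ[v2])/3.0 - iz;
    if (nxn*cx + nyn*cy + nzn*cz >= 0) {
      FA.push_back(v0); FB.push_back(v1); FC.push_back(v2);
    } else {
      FA.push_back(v0); FB.push_back(v2); FC.push_back(v1);
    }
  };
  // Kuhn 6-tetrahedra decomposition sharing the 0-7 main diagonal:
  // translation-invariant, so face triangulations match across cells
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
  };
  // cube corner offsets (dx,dy,dz) for corner index b0..b7 = x + 2y + 4z
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        uint64_t corner[8];
        double cf[8];
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          corner[c] = nid(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
          cf[c] = fval(corner[c]);
          if (cf[c] > iso) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          uint64_t n0 = corner[tets[t][0]], n1 = corner[tets[t][1]];
          uint64_t n2 = corner[tets[t][2]], n3 = corner[tets[t][3]];
          bool b0 = fval(n0) > iso, b1 = fval(n1) > iso;
          bool b2 = fval(n2) > iso, b3 = fval(n3) > iso;
          int nin = b0 + b1 + b2 + b3;
          if (nin == 0 || nin == 4) continue;
          uint64_t in[4], out[4];
          int ni = 0, no = 0;
          uint64_t nds[4] = {n0, n1, n2, n3};
          bool bs[4] = {b0, b1, b2, b3};
          for (int c = 0; c < 4; ++c) {
            if (bs[c]) in[ni++] = nds[c]; else out[no++] = nds[c];
          }
          if (nin == 1) {
            int va = edge_vertex(in[0], out[0]);
            int vb = edge_vertex(in[0], out[1]);
            int vc = edge_vertex(in[0], out[2]);
            emit(va, vb, vc, in[0]);
          } else if (nin == 3) {
            int va = edge_vertex(in[0], out[0]);
            int vb = edge_vertex(in[1], out[0]);
            int vc = edge_vertex(in[2], out[0]);
            emit(va, vb, vc, in[0]);
          } else {  // 2 in, 2 out -> quad
            int v00 = edge_vertex(in[0], out[0]);
            int v01 = edge_vertex(in[0], out[1]);
            int v11 = edge_vertex(in[1], out[1]);
            int v10 = edge_vertex(in[1], out[0]);
            emit(v00, v01, v11, in[0]);
            emit(v00, v11, v10, in[0]);
          }
        }
      }
    }
  }
  const int nv = (int)VX.size();
  NumericMatrix Vout(nv, 3);
  for (int i = 0; i < nv; ++i) {
    Vout(i, 0) = VX[i]; Vout(i, 1) = VY[i]; Vout(i, 2) = VZ[i];
  }
  IntegerMatrix Fout((int)FA.size(), 3);
  for (int i = 0; i < (int)FA.size(); ++i) {
    Fout(i, 0) = FA[i] + 1; Fout(i, 1) = FB[i] + 1; Fout(i, 2) = FC[i] + 1;
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}

// ---- Felzenszwalb squared EDT ---------------------------------------------

static void edt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                  std::vector<int>& v, std::vector<double>& zbuf) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = R_NegInf;
  zbuf[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= zbuf[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (in voxel units) to the nearest TRUE voxel.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e18;
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : INF;
  int nmax = std::max({nx, ny, nz});
  std::vector<double> f(nmax), dd(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      edt1d(f, dd, nx, v, zbuf);
      for (int i = 0; i < nx; ++i) d[base + i] = dd[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = d[base + (R_xlen_t)j * nx];
      edt1d(f, dd, ny, v, zbuf);
      for (int j = 0; j < ny; ++j) d[base + (R_xlen_t)j * nx] = dd[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = d[base + (R_xlen_t)k * nx * ny];
      edt1d(f, dd, nz, v, zbuf);
      for (int k = 0; k < nz; ++k) d[base + (R_xlen_t)k * nx * ny] = dd[k];
    }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = d[i];
  return out;
}

// ---- connected components (6-connectivity) --------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector occ, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!occ[s] || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx), j = (int)((cur / nx) % ny), k = (int)(cur / ((R_xlen_t)nx * ny));
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t id = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
        if (occ[id] && lab[id] == 0) { lab[id] = next; stack.push_back(id); }
      }
    }
  }
  return lab;
}

// ---- Taubin lambda/mu smoothing -------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_taubin_smooth(NumericMatrix V, IntegerMatrix F, int iters,
                                double lambda, double mu) {
  const int nv = V.nrow(), nf = F.nrow();
  std::vector<std::vector<int>> nbr(nv);
  for (int f = 0; f < nf; ++f) {
    int a = F(f,0), b = F(f,1), c = F(f,2);
    nbr[a].push_back(b); nbr[a].push_back(c);
    nbr[b].push_back(a); nbr[b].push_back(c);
    nbr[c].push_back(a); nbr[c].push_back(b);
  }
  for (int i = 0; i < nv; ++i) {
    std::sort(nbr[i].begin(), nbr[i].end());
    nbr[i].erase(std::unique(nbr[i].begin(), nbr[i].end()), nbr[i].end());
  }
  NumericMatrix X = clone(V);
  NumericMatrix D(nv, 3);
  for (int it = 0; it < iters; ++it) {
    for (int pass = 0; pass < 2; ++pass) {
      double w = pass == 0 ? lambda : mu;
      for (int i = 0; i < nv; ++i) {
        if (nbr[i].empty()) { D(i,0)=D(i,1)=D(i,2)=0; continue; }
        double sx = 0, sy = 0, sz = 0;
        for (int jn : nbr[i]) { sx += X(jn,0); sy += X(jn,1); sz += X(jn,2); }
        double m = (double)nbr[i].size();
        D(i,0) = sx/m - X(i,0); D(i,1) = sy/m - X(i,1); D(i,2) = sz/m - X(i,2);
      }
      for (int i = 0; i < nv; ++i) {
        X(i,0) += w * D(i,0); X(i,1) += w * D(i,1); X(i,2) += w * D(i,2);
      }
    }
  }
  return X;
}

// ---- vertex merge (STL loading) -------------------------------------------

// [[Rcpp::export]]
List cpp_merge_vertices(NumericMatrix V, IntegerMatrix F, double tol) {
  const int nv = V.nrow();
  std::unordered_map<uint64_t, std::vector<int>> buckets;
  auto key = [&](long long qi, long long qj, long long qk) -> uint64_t {
    uint64_t h = 1469598103934665603ULL;
    long long q[3] = {qi, qj, qk};
    for (int t = 0; t < 3; ++t) {
      h ^= (uint64_t)q[t] + 0x9e3779b97f4a7c15ULL;
      h *= 1099511628211ULL;
    }
    return h;
  };
  std::vector<int> remap(nv, -1);
  std::vector<int> keep;
  keep.reserve(nv);
  for (int i = 0; i < nv; ++i) {
    long long qi = (long long)std::llround(V(i,0) / tol);
    long long qj = (long long)std::llround(V(i,1) / tol);
    long long qk = (long long)std::llround(V(i,2) / tol);
    bool found = false;
    // probe neighbouring quantization cells to avoid boundary misses
    for (long long di = -1; di <= 1 && !found; ++di)
      for (long long dj = -1; dj <= 1 && !found; ++dj)
        for (long long dk = -1; dk <= 1 && !found; ++dk) {
          auto it = buckets.find(key(qi+di, qj+dj, qk+dk));
          if (it == buckets.end()) continue;
          for (int cand : it->second) {
            if (std::fabs(V(cand,0) - V(i,0)) <= tol &&
                std::fabs(V(cand,1) - V(i,1)) <= tol &&
                std::fabs(V(cand,2) - V(i,2)) <= tol) {
              remap[i] = remap[cand];
              found = true;
              break;
            }
          }
        }
    if (!found) {
      remap[i] = (int)keep.size();
      keep.push_back(i);
      buckets[key(qi, qj, qk)].push_back(i);
    }
  }
  NumericMatrix Vout((int)keep.size(), 3);
  for (size_t i = 0; i < keep.size(); ++i) {
    Vout(i,0) = V(keep[i],0); Vout(i,1) = V(keep[i],1); Vout(i,2) = V(keep[i],2);
  }
  IntegerMatrix Fout(F.nrow(), 3);
  for (int f = 0; f < F.nrow(); ++f)
    for (int c = 0; c < 3; ++c)
      Fout(f, c) = remap[F(f, c)] + 1;
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}

// ---- 3x3x3 box smoothing of a scalar grid ---------------------------------

// [[Rcpp::export]]
NumericVector cpp_box_smooth(NumericVector field, IntegerVector dims,
                             int iters) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(field.begin(), field.end()), b(n);
  for (int it = 0; it < iters; ++it) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double s = 0;
          int m = 0;
          for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di) {
                int ii = i+di, jj = j+dj, kk = k+dk;
                if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                  continue;
                s += a[(R_xlen_t)kk*nx*ny + (R_xlen_t)jj*nx + ii];
                ++m;
              }
          b[(R_xlen_t)k*nx*ny + (R_xlen_t)j*nx + i] = s / m;
        }
    std::swap(a, b);
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = a[i];
  return out;
}
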