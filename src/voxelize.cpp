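#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Watertight-union voxelization by ray parity.
//
// The surface is a soup of closed triangulated components (e.g. a capped
// vessel tube plus a sac sphere); a point is inside the lumen if it is inside
// ANY closed component. Parity is counted per component along +y rays, one
// ray per (x,z) voxel column, with a small deterministic jitter of the ray
// origin to avoid edge/vertex degeneracies.
//
// vertices: n x 3 (mm), triangles: m x 3 (0-based), comp: m (1-based ids)
// origin: lower corner of voxel (0,0,0); h: spacing; dims: nx,ny,nz
// returns integer vector length nx*ny*nz (0 outside, 1 inside), x fastest.
// [[Rcpp::export]]
IntegerVector cpp_voxelize_parity(NumericMatrix vertices, IntegerMatrix triangles,
                                  IntegerVector comp, NumericVector origin,
                                  double h, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int m = triangles.nrow();
  IntegerVector out(static_cast<R_xlen_t>(nx) * ny * nz, 0);
  const double jx = 0.012345 * h, jz = 0.023456 * h;  // fixed jitter
  int ncomp = 0;
  for (int t = 0; t < m; ++t) ncomp = std::max(ncomp, comp[t]);

  // crossings[col] = y-values where rays cross the current component
  std::vector< std::vector<double> > crossings(static_cast<size_t>(nx) * nz);

  for (int c = 1; c <= ncomp; ++c) {
    for (auto &v : crossings) v.clear();
    for (int t = 0; t < m; ++t) {
      if (comp[t] != c) continue;
      const int i0 = triangles(t, 0), i1 = triangles(t, 1), i2 = triangles(t, 2);
      const double ax = vertices(i0, 0), ay = vertices(i0, 1), az = vertices(i0, 2);
      const double bx = vertices(i1, 0), by = vertices(i1, 1), bz = vertices(i1, 2);
      const double cx = vertices(i2, 0), cy = vertices(i2, 1), cz = vertices(i2, 2);
      // projected bbox in voxel columns
      double xmin = std::min(ax, std::min(bx, cx)), xmax = std::max(ax, std::max(bx, cx));
      double zmin = std::min(az, std::min(bz, cz)), zmax = std::max(az, std::max(bz, cz));
      int ia = std::max(0, (int)std::floor((xmin - origin[0]) / h - 1.0));
      int ib = std::min(nx - 1, (int)std::ceil((xmax - origin[0]) / h + 1.0));
      int ka = std::max(0, (int)std::floor((zmin - origin[2]) / h - 1.0));
      int kb = std::min(nz - 1, (int)std::ceil((zmax - origin[2]) / h + 1.0));
      const double e1x = bx - ax, e1z = bz - az, e2x = cx - ax, e2z = cz - az;
      const double det = e1x * e2z - e2x * e1z;
      if (std::fabs(det) < 1e-14) continue;  // projected-degenerate triangle
      for (int i = ia; i <= ib; ++i) {
        const double px = origin[0] + (i + 0.5) * h + jx - ax;
        for (int k = ka; k <= kb; ++k) {
          const double pz = origin[2] + (k + 0.5) * h + jz - az;
          const double u = (px * e2z - e2x * pz) / det;
          const double v = (e1x * pz - px * e1z) / det;
          if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
          const double y = ay + u * (by - ay) + v * (cy - ay);
          crossings[static_cast<size_t>(i) * nz + k].push_back(y);
        }
      }
    }
    // parity fill per column
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) {
        std::vector<double> &cr = crossings[static_cast<size_t>(i) * nz + k];
        if (cr.size() < 2) continue;
        std::sort(cr.begin(), cr.end());
        const size_t np = cr.size() / 2;
        for (size_t p = 0; p < np; ++p) {
          const double y0 = cr[2 * p], y1 = cr[2 * p + 1];
          int ja = std::max(0, (int)std::ceil((y0 - origin[1]) / h - 0.5));
          int jb = std::min(ny - 1, (int)std::floor((y1 - origin[1]) / h - 0.5));
          for (int j = ja; j <= jb; ++j)
            out[i + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k)] = 1;
        }
      }
    }
  }
  return out;
}

// 6-connected flood fill over non-solid labels starting from seed voxels.
// labels: 0 = solid, >0 = open; seeds: 0-based linear indices.
// returns logical mask of reached voxels.
// [[Rcpp::export]]
LogicalVector cpp_flood_fill(IntegerVector labels, IntegerVector dims,
                             IntegerVector seeds) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  LogicalVector seen(n, false);
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < seeds.size(); ++s) {
    R_xlen_t idx = seeds[s];
    if (labels[idx] != 0 && !seen[idx]) { seen[idx] = true; stack.push_back(idx); }
  }
  const R_xlen_t sx = 1, sy = nx, sz = static_cast<R_xlen_t>(nx) * ny;
  while (!stack.empty()) {
    R_xlen_t idx = stack.back(); stack.pop_back();
    const int i = idx % nx, j = (idx / nx) % ny, k = idx / (static_cast<R_xlen_t>(nx) * ny);
    const R_xlen_t nb[6] = { idx - sx, idx + sx, idx - sy, idx + sy, idx - sz, idx + sz };
    const bool ok[6] = { i > 0, i < nx - 1, j > 0, j < ny - 1, k > 0, k < nz - 1 };
    for (int q = 0; q < 6; ++q) {
      if (ok[q] && labels[nb[q]] != 0 && !seen[nb[q]]) {
        seen[nb[q]] = true;
        stack.push_back(nb[q]);
      }
    }
  }
  return seen;
}

// Sub-voxel wall distances for interpolated (Bouzidi) bounce-back.
//
// For every lattice link of a fluid node whose pull-neighbor is solid, finds
// the fraction (0,1] of the link length at which the triangulated surface is
// crossed, via Moeller-Trumbore segment-triangle intersection over a uniform
// spatial hash of the triangles. Links with no detected crossing fall back
// to 0.5 (halfway bounce-back).
// [[Rcpp::export]]
NumericMatrix cpp_link_fractions(NumericMatrix vertices, IntegerMatrix triangles,
                                 NumericVector origin, double h, IntegerVector dims,
                                 NumericMatrix centers, IntegerMatrix neigh,
                                 IntegerMatrix evec) {
  const int n = centers.nrow(), m = triangles.nrow();
  NumericMatrix frac(n, 19);
  std::fill(frac.begin(), frac.end(), 0.5);

  // hash triangles into cells of size 2h
  const double cell = 2.0 * h;
  const int cx = (int)std::ceil(dims[0] * h / cell) + 1;
  const int cy = (int)std::ceil(dims[1] * h / cell) + 1;
  const int cz = (int)std::ceil(dims[2] * h / cell) + 1;
  std::vector< std::vector<int> > bins(static_cast<size_t>(cx) * cy * cz);
  auto cellof = [&](double x, double y, double z, int &i, int &j, int &k) {
    i = std::min(cx - 1, std::max(0, (int)((x - origin[0]) / cell)));
    j = std::min(cy - 1, std::max(0, (int)((y - origin[1]) / cell)));
    k = std::min(cz - 1, std::max(0, (int)((z - origin[2]) / cell)));
  };
  for (int t = 0; t < m; ++t) {
    double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
    for (int v = 0; v < 3; ++v) {
      const int iv = triangles(t, v);
      for (int d = 0; d < 3; ++d) {
        lo[d] = std::min(lo[d], vertices(iv, d));
        hi[d] = std::max(hi[d], vertices(iv, d));
      }
    }
    int ia, ja, ka, ib, jb, kb;
    cellof(lo[0], lo[1], lo[2], ia, ja, ka);
    cellof(hi[0], hi[1], hi[2], ib, jb, kb);
    for (int i = ia; i <= ib; ++i)
      for (int j = ja; j <= jb; ++j)
        for (int k = ka; k <= kb; ++k)
          bins[(static_cast<size_t>(i) * cy + j) * cz + k].push_back(t);
  }

  for (int nd = 0; nd < n; ++nd) {
    for (int q = 1; q < 19; ++q) {
      if (neigh(nd, q) >= 0) continue;
      // pull-neighbor x - e_q is solid: wall crossed along -e_q
      const double dx = -evec(q, 0) * h, dy = -evec(q, 1) * h, dz = -evec(q, 2) * h;
      const double ox = centers(nd, 0), oy = centers(nd, 1), oz = centers(nd, 2);
      double best = 2.0;
      int ci0, cj0, ck0, ci1, cj1, ck1;
      cellof(std::min(ox, ox + dx), std::min(oy, oy + dy), std::min(oz, oz + dz),
             ci0, cj0, ck0);
      cellof(std::max(ox, ox + dx), std::max(oy, oy + dy), std::max(oz, oz + dz),
             ci1, cj1, ck1);
      for (int ci = ci0; ci <= ci1; ++ci)
        for (int cj = cj0; cj <= cj1; ++cj)
          for (int ck = ck0; ck <= ck1; ++ck) {
            const std::vector<int> &lst = bins[(static_cast<size_t>(ci) * cy + cj) * cz + ck];
            for (size_t li = 0; li < lst.size(); ++li) {
              const int t = lst[li];
              const int i0 = triangles(t, 0), i1 = triangles(t, 1), i2 = triangles(t, 2);
              const double e1x = vertices(i1,0) - vertices(i0,0);
              const double e1y = vertices(i1,1) - vertices(i0,1);
              const double e1z = vertices(i1,2) - vertices(i0,2);
              const double e2x = vertices(i2,0) - vertices(i0,0);
              const double e2y = vertices(i2,1) - vertices(i0,1);
              const double e2z = vertices(i2,2) - vertices(i0,2);
              const double px = dy * e2z - dz * e2y;
              const double py = dz * e2x - dx * e2z;
              const double pz = dx * e2y - dy * e2x;
              const double det = e1x * px + e1y * py + e1z * pz;
              if (std::fabs(det) < 1e-14) continue;
              const double inv = 1.0 / det;
              const double tx = ox - vertices(i0,0);
              const double ty = oy - vertices(i0,1);
              const double tz = oz - vertices(i0,2);
              const double u = (tx * px + ty * py + tz * pz) * inv;
              if (u < -1e-9 || u > 1.0 + 1e-9) continue;
              const double qx = ty * e1z - tz * e1y;
              const double qy = tz * e1x - tx * e1z;
              const double qz = tx * e1y - ty * e1x;
              const double v = (dx * qx + dy * qy + dz * qz) * inv;
              if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
              const double tt = (e2x * qx + e2y * qy + e2z * qz) * inv;
              if (tt > 1e-9 && tt < best) best = tt;
            }
          }
      if (best <= 1.0) frac(nd, q) = std::min(1.0, std::max(1e-3, best));
    }
  }
  return frac;
}
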