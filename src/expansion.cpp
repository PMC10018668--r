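#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel index convention: voxel (i,j,k), 0-based, center at
// origin + (i,j,k) * spacing, linear index i + nx*(j + ny*k).

// Mark voxels whose center lies inside any of the given spheres.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_spheres(NumericVector origin, double spacing,
                                    IntegerVector shape,
                                    NumericMatrix centers,
                                    NumericVector radii) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  LogicalVector occ((R_xlen_t)nx * ny * nz);
  for (int s = 0; s < centers.nrow(); ++s) {
    const double cx = centers(s, 0), cy = centers(s, 1), cz = centers(s, 2);
    const double r = radii[s], r2 = r * r;
    int i0 = (int)std::ceil((cx - r - origin[0]) / spacing);
    int i1 = (int)std::floor((cx + r - origin[0]) / spacing);
    int j0 = (int)std::ceil((cy - r - origin[1]) / spacing);
    int j1 = (int)std::floor((cy + r - origin[1]) / spacing);
    int k0 = (int)std::ceil((cz - r - origin[2]) / spacing);
    int k1 = (int)std::floor((cz + r - origin[2]) / spacing);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * spacing - cz, dz2 = dz * dz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * spacing - cy, d2 = dz2 + dy * dy;
        if (d2 > r2) continue;
        const double rem = r2 - d2;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * spacing - cx;
          if (dx * dx <= rem)
            occ[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
        }
      }
    }
  }
  return occ;
}

// PTV occupancy: start from the CTV occupancy and stamp a ball of radius
// radii[s] around each boundary sample (union-of-balls nonuniform dilation).
// [[Rcpp::export]]
LogicalVector cpp_stamp_balls(NumericVector origin, double spacing,
                              IntegerVector shape, LogicalVector ctv,
                              NumericMatrix samples, NumericVector radii) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  if ((R_xlen_t)ctv.size() != (R_xlen_t)nx * ny * nz)
    stop("occupancy length does not match grid shape");
  LogicalVector occ = clone(ctv);
  for (int s = 0; s < samples.nrow(); ++s) {
    const double px = samples(s, 0), py = samples(s, 1), pz = samples(s, 2);
    const double r = radii[s], r2 = r * r;
    int i0 = (int)std::ceil((px - r - origin[0]) / spacing);
    int i1 = (int)std::floor((px + r - origin[0]) / spacing);
    int j0 = (int)std::ceil((py - r - origin[1]) / spacing);
    int j1 = (int)std::floor((py + r - origin[1]) / spacing);
    int k0 = (int)std::ceil((pz - r - origin[2]) / spacing);
    int k1 = (int)std::floor((pz + r - origin[2]) / spacing);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * spacing - pz, dz2 = dz * dz;
      if (dz2 > r2) continue;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * spacing - py, d2 = dz2 + dy * dy;
        if (d2 > r2) continue;
        const double rem = r2 - d2;
        const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * spacing - px;
          if (dx * dx <= rem) occ[base + i] = true;
        }
      }
    }
  }
  return occ;
}

// Mark voxels whose center lies inside a closed triangle mesh, by parity of
// ray-triangle crossings along a fixed slightly-skew direction (robust
// against rays grazing axis-aligned faces).
// [[Rcpp::export]]
LogicalVector cpp_rasterize_mesh(NumericVector origin, double spacing,
                                 IntegerVector shape,
                                 NumericMatrix vertices,
                                 IntegerMatrix faces) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  LogicalVector occ((R_xlen_t)nx * ny * nz);
  const int nf = faces.nrow();
  const double dx = 1.0, dy = 2.923e-4, dz = 7.071e-4;  // ray direction
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const double ox = origin[0] + i * spacing;
        const double oy = origin[1] + j * spacing;
        const double oz = origin[2] + k * spacing;
        int crossings = 0;
        for (int t = 0; t < nf; ++t) {
          const int a = faces(t, 0) - 1, b = faces(t, 1) - 1, c = faces(t, 2) - 1;
          const double e1x = vertices(b, 0) - vertices(a, 0);
          const double e1y = vertices(b, 1) - vertices(a, 1);
          const double e1z = vertices(b, 2) - vertices(a, 2);
          const double e2x = vertices(c, 0) - vertices(a, 0);
          const double e2y = vertices(c, 1) - vertices(a, 1);
          const double e2z = vertices(c, 2) - vertices(a, 2);
          // Moller-Trumbore
          const double hx = dy * e2z - dz * e2y;
          const double hy = dz * e2x - dx * e2z;
          const double hz = dx * e2y - dy * e2x;
          const double det = e1x * hx + e1y * hy + e1z * hz;
          if (std::fabs(det) < 1e-12) continue;
          const double inv = 1.0 / det;
          const double sx = ox - vertices(a, 0);
          const double sy = oy - vertices(a, 1);
          const double sz = oz - vertices(a, 2);
          const double u = inv * (sx * hx + sy * hy + sz * hz);
          if (u < 0.0 || u > 1.0) continue;
          const double qx = sy * e1z - sz * e1y;
          const double qy = sz * e1x - sx * e1z;
          const double qz = sx * e1y - sy * e1x;
          const double v = inv * (dx * qx + dy * qy + dz * qz);
          if (v < 0.0 || u + v > 1.0) continue;
          const double tt = inv * (e2x * qx + e2y * qy + e2z * qz);
          if (tt > 0.0) ++crossings;
        }
        if (crossings % 2 == 1)
          occ[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  return occ;
}
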