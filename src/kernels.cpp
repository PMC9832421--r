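// Inner loops shared by warping, projection and reconstruction.
// Conventions (fixed package-wide):
//  - volumes are cubic arma::cube with the first index along x;
//  - voxel (i,j,k) sits at centred coordinate (i-c, j-c, k-c), c = floor(n/2);
//  - trilinear interpolation everywhere; samples outside the box read 0;
//  - cpp_backproject is the exact transpose of cpp_project (same weights),
//    which makes the ART adjoint exact by construction.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double tri_sample(const cube &v, double x, double y, double z) {
  const int n0 = v.n_rows, n1 = v.n_cols, n2 = v.n_slices;
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
  if (x0 < -1 || y0 < -1 || z0 < -1 || x0 >= n0 || y0 >= n1 || z0 >= n2)
    return 0.0;
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  if (x0 >= 0 && y0 >= 0 && z0 >= 0 && x0 + 1 < n0 && y0 + 1 < n1 &&
      z0 + 1 < n2) {
    // interior fast path: no per-corner bounds checks
    const double *p = v.memptr();
    const uword sx = 1, sy = v.n_rows, sz = v.n_rows * v.n_cols;
    const double *q = p + x0 * sx + y0 * sy + z0 * sz;
    const double c00 = q[0] * (1 - fx) + q[sx] * fx;
    const double c10 = q[sy] * (1 - fx) + q[sy + sx] * fx;
    const double c01 = q[sz] * (1 - fx) + q[sz + sx] * fx;
    const double c11 = q[sz + sy] * (1 - fx) + q[sz + sy + sx] * fx;
    return (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
           (c01 * (1 - fy) + c11 * fy) * fz;
  }
  double acc = 0.0;
  for (int dx = 0; dx <= 1; ++dx) {
    const int xi = x0 + dx;
    if (xi < 0 || xi >= n0) continue;
    const double wx = dx ? fx : 1.0 - fx;
    for (int dy = 0; dy <= 1; ++dy) {
      const int yi = y0 + dy;
      if (yi < 0 || yi >= n1) continue;
      const double wy = dy ? fy : 1.0 - fy;
      for (int dz = 0; dz <= 1; ++dz) {
        const int zi = z0 + dz;
        if (zi < 0 || zi >= n2) continue;
        const double wz = dz ? fz : 1.0 - fz;
        acc += wx * wy * wz * v(xi, yi, zi);
      }
    }
  }
  return acc;
}

static inline void tri_scatter(cube &v, double x, double y, double z,
                               double val) {
  const int n0 = v.n_rows, n1 = v.n_cols, n2 = v.n_slices;
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
  if (x0 < -1 || y0 < -1 || z0 < -1 || x0 >= n0 || y0 >= n1 || z0 >= n2)
    return;
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  for (int dx = 0; dx <= 1; ++dx) {
    const int xi = x0 + dx;
    if (xi < 0 || xi >= n0) continue;
    const double wx = dx ? fx : 1.0 - fx;
    for (int dy = 0; dy <= 1; ++dy) {
      const int yi = y0 + dy;
      if (yi < 0 || yi >= n1) continue;
      const double wy = dy ? fy : 1.0 - fy;
      for (int dz = 0; dz <= 1; ++dz) {
        const int zi = z0 + dz;
        if (zi < 0 || zi >= n2) continue;
        const double wz = dz ? fz : 1.0 - fz;
        v(xi, yi, zi) += wx * wy * wz * val;
      }
    }
  }
}

// Gather warp of a volume under a Zernike3D field: out(r) = vol(r + g(r)).
// ijk: (nball x 3) 0-based voxel indices inside the unit ball;
// Z:   (nball x K) basis values at those voxels;
// alpha: (K x 3) coefficients in unit-ball units;
// rvox: scale_radius expressed in voxels (converts g to voxel units).
// Voxels outside the ball carry g = 0 and are returned untouched, so an
// all-zero alpha returns the input bit-for-bit.
// [[Rcpp::export]]
arma::cube cpp_warp_coeffs(const arma::cube &vol, const arma::mat &ijk,
                           const arma::mat &Z, const arma::mat &alpha,
                           double rvox) {
  cube out(vol);
  if (!any(any(alpha != 0.0))) return out;
  const mat disp = Z * alpha * rvox; // (nball x 3), voxel units
  const uword nb = ijk.n_rows;
  for (uword q = 0; q < nb; ++q) {
    const double x = ijk(q, 0) + disp(q, 0);
    const double y = ijk(q, 1) + disp(q, 1);
    const double z = ijk(q, 2) + disp(q, 2);
    out((uword)ijk(q, 0), (uword)ijk(q, 1), (uword)ijk(q, 2)) =
        tri_sample(vol, x, y, z);
  }
  return out;
}

// Real-space projection: rotate the sampling grid by the pose and sum along
// the viewing axis. Rt maps projection-frame coordinates to the reference
// frame (Rt = t(A) for pose matrix A). scale = voxel size (line-integral
// element).
// [[Rcpp::export]]
arma::mat cpp_project(const arma::cube &vol, const arma::mat &Rt,
                      double scale) {
  const int n = vol.n_rows;
  const double c = std::floor(n / 2.0);
  mat img(n, n, fill::zeros);
  const double r00 = Rt(0, 0), r01 = Rt(0, 1), r02 = Rt(0, 2);
  const double r10 = Rt(1, 0), r11 = Rt(1, 1), r12 = Rt(1, 2);
  const double r20 = Rt(2, 0), r21 = Rt(2, 1), r22 = Rt(2, 2);
  for (int iy = 0; iy < n; ++iy) {
    const double yp = iy - c;
    for (int ix = 0; ix < n; ++ix) {
      const double xp = ix - c;
      double acc = 0.0;
      // base point at zp = -c, then step by the third column of Rt
      double rx = r00 * xp + r01 * yp + r02 * (-c) + c;
      double ry = r10 * xp + r11 * yp + r12 * (-c) + c;
      double rz = r20 * xp + r21 * yp + r22 * (-c) + c;
      for (int iz = 0; iz < n; ++iz) {
        acc += tri_sample(vol, rx, ry, rz);
        rx += r02;
        ry += r12;
        rz += r22;
      }
      img(ix, iy) = acc * scale;
    }
  }
  return img;
}

// Exact transpose of cpp_project with respect to the Euclidean inner
// products: <project(v), i> = <v, backproject(i)> for every v, i.
// [[Rcpp::export]]
arma::cube cpp_backproject(const arma::mat &img, int n, const arma::mat &Rt,
                           double scale) {
  const double c = std::floor(n / 2.0);
  cube vol(n, n, n, fill::zeros);
  const double r00 = Rt(0, 0), r01 = Rt(0, 1), r02 = Rt(0, 2);
  const double r10 = Rt(1, 0), r11 = Rt(1, 1), r12 = Rt(1, 2);
  const double r20 = Rt(2, 0), r21 = Rt(2, 1), r22 = Rt(2, 2);
  for (int iy = 0; iy < n; ++iy) {
    const double yp = iy - c;
    for (int ix = 0; ix < n; ++ix) {
      const double xp = ix - c;
      const double val = img(ix, iy) * scale;
      if (val == 0.0) continue;
      double rx = r00 * xp + r01 * yp + r02 * (-c) + c;
      double ry = r10 * xp + r11 * yp + r12 * (-c) + c;
      double rz = r20 * xp + r21 * yp + r22 * (-c) + c;
      for (int iz = 0; iz < n; ++iz) {
        tri_scatter(vol, rx, ry, rz, val);
        rx += r02;
        ry += r12;
        rz += r22;
      }
    }
  }
  return vol;
}

// Trilinear sampling of a volume at arbitrary voxel-unit coordinates
// (pts: n x 3, 0-based voxel units). Used by oracles and model rendering.
// [[Rcpp::export]]
arma::vec cpp_trilinear(const arma::cube &vol, const arma::mat &pts) {
  const uword n = pts.n_rows;
  vec out(n);
  for (uword q = 0; q < n; ++q)
    out(q) = tri_sample(vol, pts(q, 0), pts(q, 1), pts(q, 2));
  return out;
}
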