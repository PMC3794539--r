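#include <Rcpp.h>
using namespace Rcpp;

// Resample a 3D array (column-major, dims nx*ny*nz) under an in-plane
// rotation of the x-z plane about the grid's geometric center.
// The target voxel (x, z) samples the source at the rotated position
// (rotation by `theta` radians, counter-clockwise in the x-z plane).
// Bilinear interpolation; samples outside the grid take `fill`.
// The y axis (axis 2) is untouched, so one weight set serves all y.
// [[Rcpp::export]]
NumericVector cpp_rotate_xz(NumericVector arr, IntegerVector dims,
                            double theta, double fill, bool nearest) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double cx = 0.5 * (nx - 1), cz = 0.5 * (nz - 1);
  const double ct = std::cos(theta), st = std::sin(theta);
  NumericVector out(arr.size());
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;

  std::vector<int> i0(nx * nz), k0(nx * nz);
  std::vector<double> wx(nx * nz), wz(nx * nz);
  std::vector<bool> ok(nx * nz);
  for (int k = 0; k < nz; ++k) {
    const double dz = k - cz;
    for (int i = 0; i < nx; ++i) {
      const double dx = i - cx;
      double xs = cx + ct * dx - st * dz;
      double zs = cz + st * dx + ct * dz;
      if (nearest) { xs = std::round(xs); zs = std::round(zs); }
      const int idx = i + nx * k;
      if (xs < 0 || xs > nx - 1 || zs < 0 || zs > nz - 1) {
        ok[idx] = false;
        continue;
      }
      ok[idx] = true;
      int ii = (int)std::floor(xs), kk = (int)std::floor(zs);
      if (ii == nx - 1) --ii;  // keep ii+1 in range when xs == nx-1
      if (kk == nz - 1) --kk;
      if (ii < 0) ii = 0;
      if (kk < 0) kk = 0;
      i0[idx] = ii; k0[idx] = kk;
      wx[idx] = xs - ii; wz[idx] = zs - kk;
    }
  }

  for (int k = 0; k < nz; ++k) {
    for (int i = 0; i < nx; ++i) {
      const int idx = i + nx * k;
      if (!ok[idx]) {
        for (int j = 0; j < ny; ++j) out[i + sy * j + sz * k] = fill;
        continue;
      }
      const R_xlen_t base = i0[idx] + sz * k0[idx];
      const double ax = wx[idx], az = wz[idx];
      const double w00 = (1 - ax) * (1 - az), w10 = ax * (1 - az);
      const double w01 = (1 - ax) * az,       w11 = ax * az;
      for (int j = 0; j < ny; ++j) {
        const R_xlen_t b = base + sy * j;
        out[i + sy * j + sz * k] =
          w00 * arr[b] + w10 * arr[b + 1] +
          w01 * arr[b + sz] + w11 * arr[b + 1 + sz];
      }
    }
  }
  return out;
}

// 1D convolution along the z axis (axis 3) with a centered odd-length
// kernel. Near the boundary the truncated kernel is renormalized to unit
// sum, so constants are preserved exactly everywhere.
// [[Rcpp::export]]
NumericVector cpp_convolve_z(NumericVector arr, IntegerVector dims,
                             NumericVector kernel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nk = kernel.size(), hw = (nk - 1) / 2;
  NumericVector out(arr.size());
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int k = 0; k < nz; ++k) {
    const int tlo = std::max(0, hw - k), thi = std::min(nk - 1, hw + (nz - 1 - k));
    double wsum = 0.0;
    for (int t = tlo; t <= thi; ++t) wsum += kernel[t];
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t row = (R_xlen_t)nx * j;
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        const R_xlen_t p = i + row;
        for (int t = tlo; t <= thi; ++t)
          acc += kernel[t] * arr[p + sz * (k + t - hw)];
        out[p + sz * k] = acc / wsum;
      }
    }
  }
  return out;
}

// Fraction of each voxel inside the union of parallel (possibly capped)
// cylinders, estimated on an ss^3 subvoxel grid. `centers` is m x 3 (mm),
// `axis` a unit vector, `radius` in mm, `half_length` may be R_PosInf.
// Voxel centers are at origin + index * spacing (0-based indices).
// [[Rcpp::export]]
NumericVector cpp_cylinder_fraction(IntegerVector dims, NumericVector spacing,
                                    NumericVector origin, NumericMatrix centers,
                                    NumericVector axis, double radius,
                                    double half_length, int ss) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int m = centers.nrow();
  const double r2 = radius * radius;
  const double ux = axis[0], uy = axis[1], uz = axis[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> off(ss);
  for (int s = 0; s < ss; ++s) off[s] = (s + 0.5) / ss - 0.5;

  R_xlen_t p = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++p) {
        const double x0 = origin[0] + i * spacing[0];
        const double y0 = origin[1] + j * spacing[1];
        const double z0 = origin[2] + k * spacing[2];
        int hits = 0;
        for (int a = 0; a < ss; ++a) {
          const double x = x0 + off[a] * spacing[0];
          for (int b = 0; b < ss; ++b) {
            const double y = y0 + off[b] * spacing[1];
            for (int c = 0; c < ss; ++c) {
              const double z = z0 + off[c] * spacing[2];
              bool inside = false;
              for (int t = 0; t < m && !inside; ++t) {
                const double vx = x - centers(t, 0);
                const double vy = y - centers(t, 1);
                const double vz = z - centers(t, 2);
                const double tt = vx * ux + vy * uy + vz * uz;
                if (std::fabs(tt) > half_length) continue;
                const double d2 = vx * vx + vy * vy + vz * vz - tt * tt;
                if (d2 <= r2) inside = true;
              }
              if (inside) ++hits;
            }
          }
        }
        out[p] = (double)hits / (ss * ss * ss);
      }
    }
  }
  return out;
}

// Fraction of each voxel inside an axis-aligned ellipsoid, ss^3 subvoxel
// supersampling, same voxel-center convention as cpp_cylinder_fraction.
// [[Rcpp::export]]
NumericVector cpp_ellipsoid_fraction(IntegerVector dims, NumericVector spacing,
                                     NumericVector origin, NumericVector center,
                                     NumericVector semiaxes, int ss) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> off(ss);
  for (int s = 0; s < ss; ++s) off[s] = (s + 0.5) / ss - 0.5;
  const double ax = semiaxes[0], ay = semiaxes[1], az = semiaxes[2];

  R_xlen_t p = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++p) {
        const double x0 = origin[0] + i * spacing[0] - center[0];
        const double y0 = origin[1] + j * spacing[1] - center[1];
        const double z0 = origin[2] + k * spacing[2] - center[2];
        // cheap reject: voxel far outside the bounding box
        if (std::fabs(x0) > ax + spacing[0] || std::fabs(y0) > ay + spacing[1] ||
            std::fabs(z0) > az + spacing[2]) {
          out[p] = 0.0;
          continue;
        }
        int hits = 0;
        for (int a = 0; a < ss; ++a) {
          const double qx = (x0 + off[a] * spacing[0]) / ax;
          const double qx2 = qx * qx;
          for (int b = 0; b < ss; ++b) {
            const double qy = (y0 + off[b] * spacing[1]) / ay;
            const double qxy = qx2 + qy * qy;
            if (qxy > 1.0) continue;
            for (int c = 0; c < ss; ++c) {
              const double qz = (z0 + off[c] * spacing[2]) / az;
              if (qxy + qz * qz <= 1.0) ++hits;
            }
          }
        }
        out[p] = (double)hits / (ss * ss * ss);
      }
    }
  }
  return out;
}
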