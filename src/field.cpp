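// Dense displacement-field machinery: separable Gaussian smoothing, trilinear
// warping, field composition/inversion, block pyramids and the Demons update.
// Displacements are stored in mm on the volume grid; arrays are (nx, ny, nz)
// column-major with x fastest, fields are (nx, ny, nz, 3).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static void smooth_axis(std::vector<double>& a, int nx, int ny, int nz,
                        int axis, const std::vector<double>& ker) {
  int h = (static_cast<int>(ker.size()) - 1) / 2;
  std::vector<double> out(a.size());
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, nx, static_cast<R_xlen_t>(nx) * ny};
  int na = n[axis];
  R_xlen_t sa = stride[axis];
  // iterate over all lines along `axis`
  int nb = n[(axis + 1) % 3], nc = n[(axis + 2) % 3];
  R_xlen_t sb = stride[(axis + 1) % 3], sc = stride[(axis + 2) % 3];
  for (int c = 0; c < nc; ++c)
    for (int b = 0; b < nb; ++b) {
      R_xlen_t base = b * sb + c * sc;
      for (int i = 0; i < na; ++i) {
        double acc = 0.0, wsum = 0.0;
        int k0 = std::max(0, i - h), k1 = std::min(na - 1, i + h);
        for (int k = k0; k <= k1; ++k) {
          double w = ker[k - i + h];
          acc += w * a[base + k * sa];
          wsum += w;
        }
        out[base + i * sa] = acc / wsum;
      }
    }
  a.swap(out);
}

static std::vector<double> gauss_kernel(double sigma) {
  int h = std::max(1, static_cast<int>(std::ceil(3.0 * sigma)));
  std::vector<double> k(2 * h + 1);
  for (int i = -h; i <= h; ++i) k[i + h] = std::exp(-0.5 * i * i / (sigma * sigma));
  return k;
}

static void smooth3(std::vector<double>& a, int nx, int ny, int nz, double sigma) {
  if (sigma <= 0.0) return;
  std::vector<double> k = gauss_kernel(sigma);
  smooth_axis(a, nx, ny, nz, 0, k);
  smooth_axis(a, nx, ny, nz, 1, k);
  smooth_axis(a, nx, ny, nz, 2, k);
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dims,
                               double sigma_vox) {
  std::vector<double> a(vol.begin(), vol.end());
  smooth3(a, dims[0], dims[1], dims[2], sigma_vox);
  return NumericVector(a.begin(), a.end());
}

static inline double trilin_clamp(const double* V, int nx, int ny, int nz,
                                  double x, double y, double z) {
  x = std::max(0.0, std::min(static_cast<double>(nx - 1), x));
  y = std::max(0.0, std::min(static_cast<double>(ny - 1), y));
  z = std::max(0.0, std::min(static_cast<double>(nz - 1), z));
  int i0 = std::min(static_cast<int>(x), nx - 2);
  int j0 = std::min(static_cast<int>(y), ny - 2);
  int k0 = std::min(static_cast<int>(z), nz - 2);
  if (nx == 1) i0 = 0;
  if (ny == 1) j0 = 0;
  if (nz == 1) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double out = 0.0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        int ii = std::min(i0 + di, nx - 1), jj = std::min(j0 + dj, ny - 1),
            kk = std::min(k0 + dk, nz - 1);
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        out += w * V[ii + static_cast<R_xlen_t>(nx) *
                     (jj + static_cast<R_xlen_t>(ny) * kk)];
      }
  return out;
}

// warped(x) = vol(x + u(x)); u in mm, grid spacing voxel mm
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector vol, NumericVector field,
                       IntegerVector dims, double voxel) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nv = static_cast<R_xlen_t>(nx) * ny * nz;
  NumericVector out(nv);
  const double* V = vol.begin();
  const double* U = field.begin();
  R_xlen_t q = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++q) {
        double x = i + U[q] / voxel;
        double y = j + U[q + nv] / voxel;
        double z = k + U[q + 2 * nv] / voxel;
        out[q] = trilin_clamp(V, nx, ny, nz, x, y, z);
      }
  return out;
}

// c(x) = a(x) + b(x + a(x))
// [[Rcpp::export]]
NumericVector cpp_compose_fields(NumericVector a, NumericVector b,
                                 IntegerVector dims, double voxel) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nv = static_cast<R_xlen_t>(nx) * ny * nz;
  NumericVector out(3 * nv);
  const double* A = a.begin();
  const double* B = b.begin();
  R_xlen_t q = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++q) {
        double x = i + A[q] / voxel;
        double y = j + A[q + nv] / voxel;
        double z = k + A[q + 2 * nv] / voxel;
        for (int c = 0; c < 3; ++c)
          out[q + c * nv] = A[q + c * nv] +
            trilin_clamp(B + c * nv, nx, ny, nz, x, y, z);
      }
  return out;
}

// fixed-point inverse: v(x) = -u(x + v(x))
// [[Rcpp::export]]
NumericVector cpp_invert_field(NumericVector u, IntegerVector dims,
                               double voxel, int iters) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nv = static_cast<R_xlen_t>(nx) * ny * nz;
  NumericVector v(3 * nv);
  const double* U = u.begin();
  for (int it = 0; it < iters; ++it) {
    NumericVector vn(3 * nv);
    R_xlen_t q = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++q) {
          double x = i + v[q] / voxel;
          double y = j + v[q + nv] / voxel;
          double z = k + v[q + 2 * nv] / voxel;
          for (int c = 0; c < 3; ++c)
            vn[q + c * nv] = -trilin_clamp(U + c * nv, nx, ny, nz, x, y, z);
        }
    v = vn;
  }
  return v;
}

// [[Rcpp::export]]
List cpp_downsample2(NumericVector vol, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int mx = std::max(1, nx / 2), my = std::max(1, ny / 2), mz = std::max(1, nz / 2);
  NumericVector out(static_cast<R_xlen_t>(mx) * my * mz);
  const double* V = vol.begin();
  R_xlen_t q = 0;
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i, ++q) {
        double acc = 0.0; int cnt = 0;
        for (int dk = 0; dk < 2; ++dk)
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              int ii = 2 * i + di, jj = 2 * j + dj, kk = 2 * k + dk;
              if (ii < nx && jj < ny && kk < nz) {
                acc += V[ii + static_cast<R_xlen_t>(nx) *
                         (jj + static_cast<R_xlen_t>(ny) * kk)];
                ++cnt;
              }
            }
        out[q] = acc / cnt;
      }
  return List::create(_["volume"] = out,
                      _["dims"] = IntegerVector::create(mx, my, mz));
}

// trilinear resample of a scalar grid to new dims (index-space linear map)
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dims,
                           IntegerVector newdims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int mx = newdims[0], my = newdims[1], mz = newdims[2];
  NumericVector out(static_cast<R_xlen_t>(mx) * my * mz);
  const double* V = vol.begin();
  double sx = (mx > 1) ? static_cast<double>(nx - 1) / (mx - 1) : 0.0;
  double sy = (my > 1) ? static_cast<double>(ny - 1) / (my - 1) : 0.0;
  double sz = (mz > 1) ? static_cast<double>(nz - 1) / (mz - 1) : 0.0;
  R_xlen_t q = 0;
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i, ++q)
        out[q] = trilin_clamp(V, nx, ny, nz, i * sx, j * sy, k * sz);
  return out;
}

// One pyramid level of symmetric-force Thirion demons.
// Returns field (mm) and per-iteration mean absolute intensity difference.
// [[Rcpp::export]]
List cpp_demons_level(NumericVector fixed, NumericVector moving,
                      NumericVector init_field, IntegerVector dims,
                      double voxel, int iters, double sigma_fluid,
                      double sigma_diff, double max_step_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nv = static_cast<R_xlen_t>(nx) * ny * nz;
  std::vector<double> ux(nv), uy(nv), uz(nv);
  for (R_xlen_t q = 0; q < nv; ++q) {
    ux[q] = init_field[q]; uy[q] = init_field[q + nv]; uz[q] = init_field[q + 2 * nv];
  }
  const double* F = fixed.begin();
  const double* M = moving.begin();
  // fixed-image gradient (central differences, per mm)
  std::vector<double> gfx(nv), gfy(nv), gfz(nv);
  {
    R_xlen_t q = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++q) {
          int ip = std::min(i + 1, nx - 1), im = std::max(i - 1, 0);
          int jp = std::min(j + 1, ny - 1), jm = std::max(j - 1, 0);
          int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
          R_xlen_t s = static_cast<R_xlen_t>(nx);
          R_xlen_t sz2 = static_cast<R_xlen_t>(nx) * ny;
          gfx[q] = (F[ip + s * j + sz2 * k] - F[im + s * j + sz2 * k]) /
                   ((ip - im) * voxel);
          gfy[q] = (F[i + s * jp + sz2 * k] - F[i + s * jm + sz2 * k]) /
                   ((jp - jm) * voxel);
          gfz[q] = (F[i + s * j + sz2 * kp] - F[i + s * j + sz2 * km]) /
                   ((kp - km) * voxel);
        }
  }
  NumericVector hist(iters);
  std::vector<double> wm(nv), dx(nv), dy(nv), dz(nv);
  double alpha2 = 1.0;  // intensity-difference normalization (Thirion)
  for (int it = 0; it < iters; ++it) {
    // warp moving
    double mad = 0.0;
    R_xlen_t q = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++q) {
          double x = i + ux[q] / voxel, y = j + uy[q] / voxel,
                 z = k + uz[q] / voxel;
          wm[q] = trilin_clamp(M, nx, ny, nz, x, y, z);
        }
    // gradient of warped moving + symmetric demons force
    q = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++q) {
          int ip = std::min(i + 1, nx - 1), im = std::max(i - 1, 0);
          int jp = std::min(j + 1, ny - 1), jm = std::max(j - 1, 0);
          int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
          R_xlen_t s = static_cast<R_xlen_t>(nx);
          R_xlen_t sz2 = static_cast<R_xlen_t>(nx) * ny;
          double gmx = (wm[ip + s * j + sz2 * k] - wm[im + s * j + sz2 * k]) /
                       ((ip - im) * voxel);
          double gmy = (wm[i + s * jp + sz2 * k] - wm[i + s * jm + sz2 * k]) /
                       ((jp - jm) * voxel);
          double gmz = (wm[i + s * j + sz2 * kp] - wm[i + s * j + sz2 * km]) /
                       ((kp - km) * voxel);
          double gx = 0.5 * (gfx[q] + gmx), gy = 0.5 * (gfy[q] + gmy),
                 gz = 0.5 * (gfz[q] + gmz);
          double diff = F[q] - wm[q];
          mad += std::fabs(diff);
          double g2 = gx * gx + gy * gy + gz * gz;
          double denom = g2 + alpha2 * diff * diff / (voxel * voxel);
          if (denom < 1e-12) { dx[q] = dy[q] = dz[q] = 0.0; continue; }
          double fac = diff / denom;
          double sx2 = fac * gx, sy2 = fac * gy, sz3 = fac * gz;
          double stepn = std::sqrt(sx2 * sx2 + sy2 * sy2 + sz3 * sz3) / voxel;
          if (stepn > max_step_vox) {
            double sc = max_step_vox / stepn;
            sx2 *= sc; sy2 *= sc; sz3 *= sc;
          }
          dx[q] = sx2; dy[q] = sy2; dz[q] = sz3;
        }
    hist[it] = mad / nv;
    smooth3(dx, nx, ny, nz, sigma_fluid);
    smooth3(dy, nx, ny, nz, sigma_fluid);
    smooth3(dz, nx, ny, nz, sigma_fluid);
    for (R_xlen_t p = 0; p < nv; ++p) {
      ux[p] += dx[p]; uy[p] += dy[p]; uz[p] += dz[p];
    }
    smooth3(ux, nx, ny, nz, sigma_diff);
    smooth3(uy, nx, ny, nz, sigma_diff);
    smooth3(uz, nx, ny, nz, sigma_diff);
  }
  NumericVector field(3 * nv);
  for (R_xlen_t p = 0; p < nv; ++p) {
    field[p] = ux[p]; field[p + nv] = uy[p]; field[p + 2 * nv] = uz[p];
  }
  return List::create(_["field"] = field, _["residual"] = hist);
}

// Jacobian determinant of x -> x + u(x), central differences.
// [[Rcpp::export]]
NumericVector cpp_jacobian_det(NumericVector field, IntegerVector dims,
                               double voxel) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nv = static_cast<R_xlen_t>(nx) * ny * nz;
  NumericVector out(nv);
  const double* U = field.begin();
  R_xlen_t s = nx;
  R_xlen_t s2 = static_cast<R_xlen_t>(nx) * ny;
  R_xlen_t q = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++q) {
        int ip = std::min(i + 1, nx - 1), im = std::max(i - 1, 0);
        int jp = std::min(j + 1, ny - 1), jm = std::max(j - 1, 0);
        int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
        double J[3][3];
        for (int c = 0; c < 3; ++c) {
          const double* Uc = U + c * nv;
          J[c][0] = (Uc[ip + s * j + s2 * k] - Uc[im + s * j + s2 * k]) /
                    ((ip - im) * voxel);
          J[c][1] = (Uc[i + s * jp + s2 * k] - Uc[i + s * jm + s2 * k]) /
                    ((jp - jm) * voxel);
          J[c][2] = (Uc[i + s * j + s2 * kp] - Uc[i + s * j + s2 * km]) /
                    ((kp - km) * voxel);
        }
        for (int c = 0; c < 3; ++c) J[c][c] += 1.0;
        out[q] = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
                 J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
                 J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  return out;
}
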