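// Structure-tensor computation, eigen-analysis and oriented adaptive
// smoothing for the tensor-based adaptive filter, plus a reference bilateral
// filter and a local MAD noise estimator.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static void conv_axis(std::vector<double>& a, int nx, int ny, int nz,
                      int axis, const std::vector<double>& ker, bool renorm) {
  int h = (static_cast<int>(ker.size()) - 1) / 2;
  std::vector<double> out(a.size());
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, nx, static_cast<R_xlen_t>(nx) * ny};
  int na = n[axis];
  R_xlen_t sa = stride[axis];
  int nb = n[(axis + 1) % 3], nc = n[(axis + 2) % 3];
  R_xlen_t sb = stride[(axis + 1) % 3], sc = stride[(axis + 2) % 3];
  (void)renorm;
  for (int c = 0; c < nc; ++c)
    for (int b = 0; b < nb; ++b) {
      R_xlen_t base = b * sb + c * sc;
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        // replicate-padded borders: zero-sum kernels stay zero-sum on
        // constants, normalized kernels stay mean-preserving
        for (int k = i - h; k <= i + h; ++k) {
          int kk = std::max(0, std::min(na - 1, k));
          acc += ker[k - i + h] * a[base + kk * sa];
        }
        out[base + i * sa] = acc;
      }
    }
  a.swap(out);
}

static std::vector<double> gkernel(double sigma, bool deriv) {
  int h = std::max(1, static_cast<int>(std::ceil(3.0 * sigma)));
  std::vector<double> k(2 * h + 1);
  double s = 0.0;
  for (int i = -h; i <= h; ++i) {
    double g = std::exp(-0.5 * i * i / (sigma * sigma));
    k[i + h] = deriv ? -i / (sigma * sigma) * g : g;
    if (!deriv) s += g;
  }
  if (!deriv)
    for (auto& v : k) v /= s;
  else {
    // scale so that response to a unit ramp is exactly 1
    double r = 0.0;
    for (int i = -h; i <= h; ++i) r += i * k[i + h];
    for (auto& v : k) v /= r;
  }
  return k;
}

// Gaussian-derivative gradients at scale sigma_g; tensor components smoothed
// at sigma_t. Returns six (nx*ny*nz) arrays: xx, yy, zz, xy, xz, yz.
// [[Rcpp::export]]
List cpp_structure_tensor(NumericVector vol, IntegerVector dims,
                          double sigma_g, double sigma_t) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nv = static_cast<R_xlen_t>(nx) * ny * nz;
  std::vector<double> g = gkernel(sigma_g, false);
  std::vector<double> d = gkernel(sigma_g, true);
  std::vector<double> gx(vol.begin(), vol.end());
  std::vector<double> gy(gx), gz(gx);
  conv_axis(gx, nx, ny, nz, 0, d, false);
  conv_axis(gx, nx, ny, nz, 1, g, false);
  conv_axis(gx, nx, ny, nz, 2, g, false);
  conv_axis(gy, nx, ny, nz, 1, d, false);
  conv_axis(gy, nx, ny, nz, 0, g, false);
  conv_axis(gy, nx, ny, nz, 2, g, false);
  conv_axis(gz, nx, ny, nz, 2, d, false);
  conv_axis(gz, nx, ny, nz, 0, g, false);
  conv_axis(gz, nx, ny, nz, 1, g, false);
  List comps(6);
  const char* nm[6] = {"xx", "yy", "zz", "xy", "xz", "yz"};
  std::vector<double> t(nv);
  for (int c = 0; c < 6; ++c) {
    for (R_xlen_t q = 0; q < nv; ++q) {
      switch (c) {
        case 0: t[q] = gx[q] * gx[q]; break;
        case 1: t[q] = gy[q] * gy[q]; break;
        case 2: t[q] = gz[q] * gz[q]; break;
        case 3: t[q] = gx[q] * gy[q]; break;
        case 4: t[q] = gx[q] * gz[q]; break;
        case 5: t[q] = gy[q] * gz[q]; break;
      }
    }
    std::vector<double> s(t);
    if (sigma_t > 0) {
      std::vector<double> k = gkernel(sigma_t, false);
      conv_axis(s, nx, ny, nz, 0, k, false);
      conv_axis(s, nx, ny, nz, 1, k, false);
      conv_axis(s, nx, ny, nz, 2, k, false);
    }
    comps[c] = NumericVector(s.begin(), s.end());
  }
  comps.attr("names") = CharacterVector(nm, nm + 6);
  return comps;
}

// Analytic eigen-decomposition of a symmetric 3x3 matrix; eigenvalues sorted
// descending, returns major (lambda1) and minor (lambda3) eigenvectors.
static void sym3_eig(const double M[6], double lam[3], double v1[3],
                     double v3[3]) {
  double xx = M[0], yy = M[1], zz = M[2], xy = M[3], xz = M[4], yz = M[5];
  double p1 = xy * xy + xz * xz + yz * yz;
  double q = (xx + yy + zz) / 3.0;
  if (p1 < 1e-30) {
    lam[0] = std::max(xx, std::max(yy, zz));
    lam[2] = std::min(xx, std::min(yy, zz));
    lam[1] = xx + yy + zz - lam[0] - lam[2];
    v1[0] = 1; v1[1] = 0; v1[2] = 0;
    v3[0] = 0; v3[1] = 0; v3[2] = 1;
    return;
  }
  double p2 = (xx - q) * (xx - q) + (yy - q) * (yy - q) + (zz - q) * (zz - q) +
              2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  double B[6];
  B[0] = (xx - q) / p; B[1] = (yy - q) / p; B[2] = (zz - q) / p;
  B[3] = xy / p; B[4] = xz / p; B[5] = yz / p;
  double detB = B[0] * (B[1] * B[2] - B[5] * B[5]) -
                B[3] * (B[3] * B[2] - B[5] * B[4]) +
                B[4] * (B[3] * B[5] - B[1] * B[4]);
  double r = detB / 2.0;
  r = std::max(-1.0, std::min(1.0, r));
  double phi = std::acos(r) / 3.0;
  lam[0] = q + 2.0 * p * std::cos(phi);
  lam[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  lam[1] = 3.0 * q - lam[0] - lam[2];
  // eigenvector for eigenvalue lam: cross products of rows of (M - lam I)
  for (int which = 0; which < 2; ++which) {
    double l = which == 0 ? lam[0] : lam[2];
    double* v = which == 0 ? v1 : v3;
    double r0[3] = {xx - l, xy, xz};
    double r1[3] = {xy, yy - l, yz};
    double r2[3] = {xz, yz, zz - l};
    double c01[3] = {r0[1] * r1[2] - r0[2] * r1[1],
                     r0[2] * r1[0] - r0[0] * r1[2],
                     r0[0] * r1[1] - r0[1] * r1[0]};
    double c02[3] = {r0[1] * r2[2] - r0[2] * r2[1],
                     r0[2] * r2[0] - r0[0] * r2[2],
                     r0[0] * r2[1] - r0[1] * r2[0]};
    double c12[3] = {r1[1] * r2[2] - r1[2] * r2[1],
                     r1[2] * r2[0] - r1[0] * r2[2],
                     r1[0] * r2[1] - r1[1] * r2[0]};
    double n01 = c01[0] * c01[0] + c01[1] * c01[1] + c01[2] * c01[2];
    double n02 = c02[0] * c02[0] + c02[1] * c02[1] + c02[2] * c02[2];
    double n12 = c12[0] * c12[0] + c12[1] * c12[1] + c12[2] * c12[2];
    double* best = c01; double bn = n01;
    if (n02 > bn) { best = c02; bn = n02; }
    if (n12 > bn) { best = c12; bn = n12; }
    if (bn < 1e-30) { v[0] = which == 0 ? 1 : 0; v[1] = 0; v[2] = which == 0 ? 0 : 1; }
    else {
      double nn = std::sqrt(bn);
      v[0] = best[0] / nn; v[1] = best[1] / nn; v[2] = best[2] / nn;
    }
  }
}

// [[Rcpp::export]]
List cpp_tensor_eig(NumericVector xx, NumericVector yy, NumericVector zz,
                    NumericVector xy, NumericVector xz, NumericVector yz) {
  R_xlen_t nv = xx.size();
  NumericVector l1(nv), l2(nv), l3(nv);
  NumericMatrix e1(nv, 3), e3(nv, 3);
  for (R_xlen_t q = 0; q < nv; ++q) {
    double M[6] = {xx[q], yy[q], zz[q], xy[q], xz[q], yz[q]};
    double lam[3], v1[3], v3[3];
    sym3_eig(M, lam, v1, v3);
    l1[q] = lam[0]; l2[q] = lam[1]; l3[q] = lam[2];
    e1(q, 0) = v1[0]; e1(q, 1) = v1[1]; e1(q, 2) = v1[2];
    e3(q, 0) = v3[0]; e3(q, 1) = v3[1]; e3(q, 2) = v3[2];
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3,
                      _["e1"] = e1, _["e3"] = e3);
}

// Oriented 1D Gaussian smoothing: per-voxel direction (unit, voxel space) and
// per-voxel sigma (voxels); taps at integer offsets up to halflen.
// [[Rcpp::export]]
NumericVector cpp_oriented_smooth(NumericVector vol, IntegerVector dims,
                                  NumericMatrix dir, NumericVector sigma,
                                  int halflen) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nv = static_cast<R_xlen_t>(nx) * ny * nz;
  NumericVector out(nv);
  const double* V = vol.begin();
  R_xlen_t q = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++q) {
        double s = sigma[q];
        if (s <= 1e-3) { out[q] = V[q]; continue; }
        double dx = dir(q, 0), dy = dir(q, 1), dz = dir(q, 2);
        double acc = V[q], wsum = 1.0;
        for (int t = 1; t <= halflen; ++t) {
          double w = std::exp(-0.5 * t * t / (s * s));
          if (w < 1e-4) break;
          for (int sgn = -1; sgn <= 1; sgn += 2) {
            double x = i + sgn * t * dx, y = j + sgn * t * dy,
                   z = k + sgn * t * dz;
            x = std::max(0.0, std::min(static_cast<double>(nx - 1), x));
            y = std::max(0.0, std::min(static_cast<double>(ny - 1), y));
            z = std::max(0.0, std::min(static_cast<double>(nz - 1), z));
            int i0 = std::min(static_cast<int>(x), std::max(nx - 2, 0));
            int j0 = std::min(static_cast<int>(y), std::max(ny - 2, 0));
            int k0 = std::min(static_cast<int>(z), std::max(nz - 2, 0));
            double fx = x - i0, fy = y - j0, fz = z - k0;
            double val = 0.0;
            for (int dk = 0; dk < 2; ++dk)
              for (int dj = 0; dj < 2; ++dj)
                for (int di = 0; di < 2; ++di) {
                  int ii = std::min(i0 + di, nx - 1);
                  int jj = std::min(j0 + dj, ny - 1);
                  int kk = std::min(k0 + dk, nz - 1);
                  double ww = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                              (dk ? fz : 1 - fz);
                  val += ww * V[ii + static_cast<R_xlen_t>(nx) *
                                (jj + static_cast<R_xlen_t>(ny) * kk)];
                }
            acc += w * val;
            wsum += w;
          }
        }
        out[q] = acc / wsum;
      }
  return out;
}

// Median absolute deviation of `res` over a cubic window (half-width hw).
// [[Rcpp::export]]
NumericVector cpp_local_mad(NumericVector res, IntegerVector dims, int hw) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nv = static_cast<R_xlen_t>(nx) * ny * nz;
  NumericVector out(nv);
  const double* R = res.begin();
  std::vector<double> buf;
  buf.reserve((2 * hw + 1) * (2 * hw + 1) * (2 * hw + 1));
  R_xlen_t q = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++q) {
        buf.clear();
        for (int dk = -hw; dk <= hw; ++dk) {
          int kk = std::max(0, std::min(nz - 1, k + dk));
          for (int dj = -hw; dj <= hw; ++dj) {
            int jj = std::max(0, std::min(ny - 1, j + dj));
            for (int di = -hw; di <= hw; ++di) {
              int ii = std::max(0, std::min(nx - 1, i + di));
              buf.push_back(R[ii + static_cast<R_xlen_t>(nx) *
                              (jj + static_cast<R_xlen_t>(ny) * kk)]);
            }
          }
        }
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        for (auto& v : buf) v = std::fabs(v - med);
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        out[q] = 1.4826 * buf[m];
      }
  return out;
}

// Reference bilateral filter (baseline for staircasing comparisons).
// [[Rcpp::export]]
NumericVector cpp_bilateral(NumericVector vol, IntegerVector dims,
                            double sigma_s, double sigma_r, int hw) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nv = static_cast<R_xlen_t>(nx) * ny * nz;
  NumericVector out(nv);
  const double* V = vol.begin();
  R_xlen_t q = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++q) {
        double c = V[q], acc = 0.0, wsum = 0.0;
        for (int dk = -hw; dk <= hw; ++dk) {
          int kk = std::max(0, std::min(nz - 1, k + dk));
          for (int dj = -hw; dj <= hw; ++dj) {
            int jj = std::max(0, std::min(ny - 1, j + dj));
            for (int di = -hw; di <= hw; ++di) {
              int ii = std::max(0, std::min(nx - 1, i + di));
              double v = V[ii + static_cast<R_xlen_t>(nx) *
                           (jj + static_cast<R_xlen_t>(ny) * kk)];
              double d2 = di * di + dj * dj + dk * dk;
              double r = v - c;
              double w = std::exp(-0.5 * d2 / (sigma_s * sigma_s)) *
                         std::exp(-0.5 * r * r / (sigma_r * sigma_r));
              acc += w * v;
              wsum += w;
            }
          }
        }
        out[q] = acc / wsum;
      }
  return out;
}
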