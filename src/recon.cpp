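// Cone-beam backprojection (FDK) and a voxel-domain ray-marching projector
// used as an independent cross-check of the analytic projector.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Filtered frames: array (n_rows, n_cols, n_frames), detector coordinates
// already rescaled to the isocenter plane (du = dv = pixel * R_F / R_FD).
// Volume grid: voxel centers at origin + index * voxel (x fastest).
// [[Rcpp::export]]
List cpp_backproject(NumericVector frames, IntegerVector fdim,
                     NumericVector angles, NumericVector weights,
                     double R_F, double du,
                     IntegerVector dims, double voxel, NumericVector origin) {
  int nr = fdim[0], nc = fdim[1], nf = fdim[2];
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;
  NumericVector vol(nvox);
  IntegerVector cover(nvox);
  double cu = 0.5 * (nc - 1), cv = 0.5 * (nr - 1);
  const double* F = frames.begin();
  double* V = vol.begin();
  int* C = cover.begin();
  for (int f = 0; f < nf; ++f) {
    double th = angles[f], w = weights[f];
    if (w == 0.0) continue;
    double ce = std::cos(th), se = std::sin(th);
    const double* Fr = F + static_cast<R_xlen_t>(f) * nr * nc;
    R_xlen_t q = 0;
    for (int k = 0; k < nz; ++k) {
      double z = origin[2] + k * voxel;
      for (int j = 0; j < ny; ++j) {
        double y = origin[1] + j * voxel;
        for (int i = 0; i < nx; ++i, ++q) {
          double x = origin[0] + i * voxel;
          double L = R_F - (x * ce + y * se);
          if (L <= 1e-6) continue;
          double U = R_F / L;
          double u = U * (-x * se + y * ce);
          double v = U * z;
          double iu = u / du + cu, iv = v / du + cv;
          int i0 = static_cast<int>(std::floor(iu));
          int j0 = static_cast<int>(std::floor(iv));
          if (i0 < 0 || i0 >= nc - 1 || j0 < 0 || j0 >= nr - 1) continue;
          double fu = iu - i0, fv = iv - j0;
          double p00 = Fr[j0 + nr * i0], p01 = Fr[j0 + nr * (i0 + 1)];
          double p10 = Fr[j0 + 1 + nr * i0], p11 = Fr[j0 + 1 + nr * (i0 + 1)];
          double val = (1 - fv) * ((1 - fu) * p00 + fu * p01) +
                       fv * ((1 - fu) * p10 + fu * p11);
          V[q] += w * U * U * val;
          C[q] += 1;
        }
      }
    }
  }
  return List::create(_["volume"] = vol, _["coverage"] = cover);
}

static inline double trilin(const double* V, int nx, int ny, int nz,
                            double x, double y, double z) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return 0.0;
  int i0 = std::min(static_cast<int>(std::floor(x)), nx - 2);
  int j0 = std::min(static_cast<int>(std::floor(y)), ny - 2);
  int k0 = std::min(static_cast<int>(std::floor(z)), nz - 2);
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double out = 0.0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        out += w * V[(i0 + di) + static_cast<R_xlen_t>(nx) *
                     ((j0 + dj) + static_cast<R_xlen_t>(ny) * (k0 + dk))];
      }
  return out;
}

// Ray-marching projection of a voxelized volume (independent oracle for the
// analytic projector; step in mm).
// [[Rcpp::export]]
NumericMatrix cpp_voxel_project_frame(NumericVector vol, IntegerVector dims,
                                      double voxel, NumericVector origin,
                                      double angle, double R_F, double R_FD,
                                      double pixel_mm, int n_rows, int n_cols,
                                      double step) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double ce = std::cos(angle), se = std::sin(angle);
  double S[3] = {R_F * ce, R_F * se, 0.0};
  double D0[3] = {(R_F - R_FD) * ce, (R_F - R_FD) * se, 0.0};
  double uh[3] = {-se, ce, 0.0};
  double cu = 0.5 * (n_cols - 1), cv = 0.5 * (n_rows - 1);
  NumericMatrix out(n_rows, n_cols);
  const double* V = vol.begin();
  // bounding sphere of the grid for march limits
  double cxr = origin[0] + 0.5 * (nx - 1) * voxel;
  double cyr = origin[1] + 0.5 * (ny - 1) * voxel;
  double czr = origin[2] + 0.5 * (nz - 1) * voxel;
  double rad = 0.5 * voxel * std::sqrt(static_cast<double>(nx) * nx +
                                       static_cast<double>(ny) * ny +
                                       static_cast<double>(nz) * nz);
  for (int j = 0; j < n_cols; ++j) {
    double uo = (j - cu) * pixel_mm;
    for (int i = 0; i < n_rows; ++i) {
      double vo = (i - cv) * pixel_mm;
      double P[3] = {D0[0] + uo * uh[0], D0[1] + uo * uh[1], vo};
      double d[3] = {P[0] - S[0], P[1] - S[1], P[2] - S[2]};
      double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
      double oc[3] = {cxr - S[0], cyr - S[1], czr - S[2]};
      double tm = oc[0] * d[0] + oc[1] * d[1] + oc[2] * d[2];
      double t0 = std::max(0.0, tm - rad), t1 = tm + rad;
      double acc = 0.0;
      for (double t = t0; t < t1; t += step) {
        double x = (S[0] + t * d[0] - origin[0]) / voxel;
        double y = (S[1] + t * d[1] - origin[1]) / voxel;
        double z = (S[2] + t * d[2] - origin[2]) / voxel;
        acc += trilin(V, nx, ny, nz, x, y, z);
      }
      out(i, j) = acc * step;
    }
  }
  return out;
}
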