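// Analytic primitive phantom: point evaluation, exact ray integrals and
// voxelization for compound ellipsoid/capsule scenes.
//
// Primitive matrix layout (one row per primitive, 10 columns):
//   0      type: 0 = axis-aligned ellipsoid, 1 = capsule (segment + radius)
//   1..3   ellipsoid center / capsule endpoint A (mm)
//   4..6   ellipsoid semi-axes / capsule endpoint B (mm)
//   7      capsule radius (mm; unused for ellipsoids)
//   8      mu (1/mm)
//   9      priority (larger wins where primitives overlap)
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Interval { double t0, t1; };

static inline bool ellipsoid_interval(const double* pr, const double* o,
                                      const double* d, Interval& iv) {
  // Scale to the unit sphere: y_i = (x_i - c_i)/a_i.
  double A = 0.0, B = 0.0, C = -1.0;
  for (int i = 0; i < 3; ++i) {
    double oi = (o[i] - pr[1 + i]) / pr[4 + i];
    double di = d[i] / pr[4 + i];
    A += di * di; B += 2.0 * oi * di; C += oi * oi;
  }
  if (A <= 0.0) return false;
  double disc = B * B - 4.0 * A * C;
  if (disc <= 0.0) return false;
  double s = std::sqrt(disc);
  iv.t0 = (-B - s) / (2.0 * A);
  iv.t1 = (-B + s) / (2.0 * A);
  return true;
}

static inline bool sphere_interval(const double* c, double r, const double* o,
                                   const double* d, Interval& iv) {
  double B = 0.0, C = -r * r, A = 0.0;
  for (int i = 0; i < 3; ++i) {
    double oi = o[i] - c[i];
    A += d[i] * d[i]; B += 2.0 * oi * d[i]; C += oi * oi;
  }
  double disc = B * B - 4.0 * A * C;
  if (disc <= 0.0) return false;
  double s = std::sqrt(disc);
  iv.t0 = (-B - s) / (2.0 * A);
  iv.t1 = (-B + s) / (2.0 * A);
  return true;
}

// Capsule is convex and equals the union of a finite cylinder and two end
// spheres, so the line intersection is the single interval spanning the
// piecewise intervals.
static inline bool capsule_interval(const double* pr, const double* o,
                                    const double* d, Interval& iv) {
  const double* A = pr + 1;
  const double* B = pr + 4;
  double r = pr[7];
  double w[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
  double L = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  bool any = false;
  double t0 = 0.0, t1 = 0.0;
  Interval s;
  if (sphere_interval(A, r, o, d, s)) { t0 = s.t0; t1 = s.t1; any = true; }
  if (sphere_interval(B, r, o, d, s)) {
    if (!any) { t0 = s.t0; t1 = s.t1; any = true; }
    else { t0 = std::min(t0, s.t0); t1 = std::max(t1, s.t1); }
  }
  if (L > 1e-12) {
    double wh[3] = {w[0] / L, w[1] / L, w[2] / L};
    double oa[3] = {o[0] - A[0], o[1] - A[1], o[2] - A[2]};
    double dw = d[0] * wh[0] + d[1] * wh[1] + d[2] * wh[2];
    double ow = oa[0] * wh[0] + oa[1] * wh[1] + oa[2] * wh[2];
    double dp[3] = {d[0] - dw * wh[0], d[1] - dw * wh[1], d[2] - dw * wh[2]};
    double op[3] = {oa[0] - ow * wh[0], oa[1] - ow * wh[1], oa[2] - ow * wh[2]};
    double a2 = dp[0] * dp[0] + dp[1] * dp[1] + dp[2] * dp[2];
    double b2 = 2.0 * (dp[0] * op[0] + dp[1] * op[1] + dp[2] * op[2]);
    double c2 = op[0] * op[0] + op[1] * op[1] + op[2] * op[2] - r * r;
    double ct0, ct1; bool cyl = false;
    if (a2 < 1e-14) {
      if (c2 <= 0.0) { ct0 = -1e30; ct1 = 1e30; cyl = true; }
    } else {
      double disc = b2 * b2 - 4.0 * a2 * c2;
      if (disc > 0.0) {
        double sq = std::sqrt(disc);
        ct0 = (-b2 - sq) / (2.0 * a2); ct1 = (-b2 + sq) / (2.0 * a2);
        cyl = true;
      }
    }
    if (cyl) {
      // clip by axial planes 0 <= s(t) = ow + t*dw <= L
      if (std::fabs(dw) < 1e-14) {
        if (ow < 0.0 || ow > L) cyl = false;
      } else {
        double ta = (0.0 - ow) / dw, tb = (L - ow) / dw;
        if (ta > tb) std::swap(ta, tb);
        ct0 = std::max(ct0, ta); ct1 = std::min(ct1, tb);
        if (ct0 >= ct1) cyl = false;
      }
    }
    if (cyl) {
      if (!any) { t0 = ct0; t1 = ct1; any = true; }
      else { t0 = std::min(t0, ct0); t1 = std::max(t1, ct1); }
    }
  }
  if (!any || t1 <= t0) return false;
  iv.t0 = t0; iv.t1 = t1;
  return true;
}

static inline bool point_inside(const double* pr, const double* x) {
  if (pr[0] < 0.5) {
    double s = 0.0;
    for (int i = 0; i < 3; ++i) {
      double y = (x[i] - pr[1 + i]) / pr[4 + i];
      s += y * y;
    }
    return s <= 1.0;
  }
  const double* A = pr + 1;
  const double* B = pr + 4;
  double r = pr[7];
  double w[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
  double L2 = w[0] * w[0] + w[1] * w[1] + w[2] * w[2];
  double xa[3] = {x[0] - A[0], x[1] - A[1], x[2] - A[2]};
  double s = 0.0;
  if (L2 > 1e-24) {
    s = (xa[0] * w[0] + xa[1] * w[1] + xa[2] * w[2]) / L2;
    s = std::max(0.0, std::min(1.0, s));
  }
  double dx = xa[0] - s * w[0], dy = xa[1] - s * w[1], dz = xa[2] - s * w[2];
  return dx * dx + dy * dy + dz * dz <= r * r;
}

// [[Rcpp::export]]
NumericVector cpp_attenuation(NumericMatrix points, NumericMatrix prims) {
  int n = points.nrow(), np = prims.nrow();
  NumericVector out(n);
  std::vector<double> P(np * 10);
  for (int p = 0; p < np; ++p)
    for (int c = 0; c < 10; ++c) P[p * 10 + c] = prims(p, c);
  for (int i = 0; i < n; ++i) {
    double x[3] = {points(i, 0), points(i, 1), points(i, 2)};
    double best_pr = -1e30, mu = 0.0;
    for (int p = 0; p < np; ++p) {
      const double* pr = &P[p * 10];
      if (pr[9] > best_pr && point_inside(pr, x)) { best_pr = pr[9]; mu = pr[8]; }
    }
    out[i] = mu;
  }
  return out;
}

// Exact line integral of the priority-resolved scene along o + t*d (|d| = 1).
static double ray_integral(const std::vector<double>& P, int np,
                           const double* o, const double* d,
                           std::vector<Interval>& ivs, std::vector<int>& idx,
                           std::vector<double>& brk) {
  ivs.clear(); idx.clear(); brk.clear();
  for (int p = 0; p < np; ++p) {
    const double* pr = &P[p * 10];
    Interval iv;
    bool hit = (pr[0] < 0.5) ? ellipsoid_interval(pr, o, d, iv)
                             : capsule_interval(pr, o, d, iv);
    if (hit) {
      ivs.push_back(iv); idx.push_back(p);
      brk.push_back(iv.t0); brk.push_back(iv.t1);
    }
  }
  if (ivs.empty()) return 0.0;
  std::sort(brk.begin(), brk.end());
  double total = 0.0;
  for (size_t k = 0; k + 1 < brk.size(); ++k) {
    double a = brk[k], b = brk[k + 1];
    if (b - a < 1e-12) continue;
    double tm = 0.5 * (a + b);
    double best_pr = -1e30, mu = 0.0;
    for (size_t j = 0; j < ivs.size(); ++j) {
      if (ivs[j].t0 <= tm && tm <= ivs[j].t1) {
        const double* pr = &P[idx[j] * 10];
        if (pr[9] > best_pr) { best_pr = pr[9]; mu = pr[8]; }
      }
    }
    total += mu * (b - a);
  }
  return total;
}

// [[Rcpp::export]]
NumericMatrix cpp_project_frame(NumericMatrix prims, double angle,
                                double R_F, double R_FD, double pixel_mm,
                                int n_rows, int n_cols) {
  int np = prims.nrow();
  std::vector<double> P(np * 10);
  for (int p = 0; p < np; ++p)
    for (int c = 0; c < 10; ++c) P[p * 10 + c] = prims(p, c);
  double e[3] = {std::cos(angle), std::sin(angle), 0.0};
  double uh[3] = {-std::sin(angle), std::cos(angle), 0.0};
  double S[3] = {R_F * e[0], R_F * e[1], 0.0};
  double D0[3] = {(R_F - R_FD) * e[0], (R_F - R_FD) * e[1], 0.0};
  double cu = 0.5 * (n_cols - 1), cv = 0.5 * (n_rows - 1);
  NumericMatrix out(n_rows, n_cols);
  std::vector<Interval> ivs; std::vector<int> idx; std::vector<double> brk;
  for (int j = 0; j < n_cols; ++j) {
    double uo = (j - cu) * pixel_mm;
    for (int i = 0; i < n_rows; ++i) {
      double vo = (i - cv) * pixel_mm;
      double Ppix[3] = {D0[0] + uo * uh[0], D0[1] + uo * uh[1], vo};
      double d[3] = {Ppix[0] - S[0], Ppix[1] - S[1], Ppix[2] - S[2]};
      double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
      out(i, j) = ray_integral(P, np, S, d, ivs, idx, brk);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_voxelize(NumericMatrix prims, IntegerVector dims,
                           double voxel, NumericVector origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int np = prims.nrow();
  std::vector<double> P(np * 10);
  for (int p = 0; p < np; ++p)
    for (int c = 0; c < 10; ++c) P[p * 10 + c] = prims(p, c);
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  R_xlen_t q = 0;
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + k * voxel;
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + j * voxel;
      for (int i = 0; i < nx; ++i, ++q) {
        double x[3] = {origin[0] + i * voxel, y, z};
        double best_pr = -1e30, mu = 0.0;
        for (int p = 0; p < np; ++p) {
          const double* pr = &P[p * 10];
          if (pr[9] > best_pr && point_inside(pr, x)) {
            best_pr = pr[9]; mu = pr[8];
          }
        }
        out[q] = mu;
      }
    }
  }
  return out;
}
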