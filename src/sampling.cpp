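#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear / nearest sampling of an axis-aligned volume at arbitrary
// physical points. Voxel (0,0,0) center sits at `origin` (mm); voxel
// centers are origin + idx * spacing. Points outside the support of the
// voxel-center lattice return `fill`.

static inline double sample_tri(const double* v, int nx, int ny, int nz,
                                double gx, double gy, double gz, double fill) {
  if (gx < 0 || gy < 0 || gz < 0 || gx > nx - 1 || gy > ny - 1 || gz > nz - 1)
    return fill;
  int x0 = (int)std::floor(gx), y0 = (int)std::floor(gy), z0 = (int)std::floor(gz);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (nx == 1) x0 = 0;
  if (ny == 1) y0 = 0;
  if (nz == 1) z0 = 0;
  double fx = gx - x0, fy = gy - y0, fz = gz - z0;
  int x1 = nx == 1 ? x0 : x0 + 1, y1 = ny == 1 ? y0 : y0 + 1, z1 = nz == 1 ? z0 : z0 + 1;
  if (nx == 1) fx = 0; if (ny == 1) fy = 0; if (nz == 1) fz = 0;
#define V(i, j, k) v[(size_t)(i) + (size_t)nx * ((size_t)(j) + (size_t)ny * (size_t)(k))]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
#undef V
}

static inline double sample_near(const double* v, int nx, int ny, int nz,
                                 double gx, double gy, double gz, double fill) {
  long ix = (long)std::lround(gx), iy = (long)std::lround(gy), iz = (long)std::lround(gz);
  if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) return fill;
  return v[(size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * (size_t)iz)];
}

// [[Rcpp::export]]
NumericVector cpp_sample_volume(NumericVector vol, IntegerVector shape,
                                NumericVector origin, NumericVector spacing,
                                NumericMatrix pts, bool nearest, double fill) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  const double* v = REAL(vol);
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    double gx = (pts(i, 0) - origin[0]) / spacing[0];
    double gy = (pts(i, 1) - origin[1]) / spacing[1];
    double gz = (pts(i, 2) - origin[2]) / spacing[2];
    out[i] = nearest ? sample_near(v, nx, ny, nz, gx, gy, gz, fill)
                     : sample_tri(v, nx, ny, nz, gx, gy, gz, fill);
  }
  return out;
}

// Cubic B-spline basis (uniform), u in [0,1)
static inline void bspl_w(double u, double* w) {
  double u2 = u * u, u3 = u2 * u;
  w[0] = (1 - 3 * u + 3 * u2 - u3) / 6.0;
  w[1] = (4 - 6 * u2 + 3 * u3) / 6.0;
  w[2] = (1 + 3 * u + 3 * u2 - 3 * u3) / 6.0;
  w[3] = u3 / 6.0;
}

// Evaluate a displacement field (mm) from cubic B-spline coefficients on a
// regular control grid. coef has dim (ncx, ncy, ncz, 3); control point
// (0,0,0) sits at corigin, spaced cspacing. Field is evaluated at the voxel
// centers of the target geometry. Control grid must cover the volume with
// one extra knot on each side (checked in R).
// [[Rcpp::export]]
NumericVector cpp_bspline_field(NumericVector coef, IntegerVector cshape,
                                NumericVector corigin, NumericVector cspacing,
                                IntegerVector shape, NumericVector origin,
                                NumericVector spacing) {
  int ncx = cshape[0], ncy = cshape[1], ncz = cshape[2];
  int nx = shape[0], ny = shape[1], nz = shape[2];
  size_t nc = (size_t)ncx * ncy * ncz, nv = (size_t)nx * ny * nz;
  const double* c = REAL(coef);
  NumericVector out((R_xlen_t)(nv * 3));
  double* o = REAL(out);
  std::vector<int> ix(nx), iy(ny), iz(nz);
  std::vector<double> wx(nx * 4), wy(ny * 4), wz(nz * 4);
  for (int i = 0; i < nx; i++) {
    double t = (origin[0] + i * spacing[0] - corigin[0]) / cspacing[0];
    int i0 = (int)std::floor(t);
    ix[i] = i0; bspl_w(t - i0, &wx[i * 4]);
  }
  for (int j = 0; j < ny; j++) {
    double t = (origin[1] + j * spacing[1] - corigin[1]) / cspacing[1];
    int j0 = (int)std::floor(t);
    iy[j] = j0; bspl_w(t - j0, &wy[j * 4]);
  }
  for (int k = 0; k < nz; k++) {
    double t = (origin[2] + k * spacing[2] - corigin[2]) / cspacing[2];
    int k0 = (int)std::floor(t);
    iz[k] = k0; bspl_w(t - k0, &wz[k * 4]);
  }
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        double acc[3] = {0, 0, 0};
        for (int c3 = 0; c3 < 4; c3++) {
          int kk = iz[k] - 1 + c3;
          if (kk < 0 || kk >= ncz) continue;
          for (int c2 = 0; c2 < 4; c2++) {
            int jj = iy[j] - 1 + c2;
            if (jj < 0 || jj >= ncy) continue;
            double wyz = wy[j * 4 + c2] * wz[k * 4 + c3];
            for (int c1 = 0; c1 < 4; c1++) {
              int ii = ix[i] - 1 + c1;
              if (ii < 0 || ii >= ncx) continue;
              double w = wx[i * 4 + c1] * wyz;
              size_t ci = (size_t)ii + (size_t)ncx * ((size_t)jj + (size_t)ncy * kk);
              acc[0] += w * c[ci];
              acc[1] += w * c[ci + nc];
              acc[2] += w * c[ci + 2 * nc];
            }
          }
        }
        size_t vi = (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
        o[vi] = acc[0]; o[vi + nv] = acc[1]; o[vi + 2 * nv] = acc[2];
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return out;
}

// Mean-squared-error between fixed and moving-warped-by-B-spline-field and
// its analytic gradient with respect to the control coefficients.
// moving lives on the same grid as fixed (pre-resampled through the affine
// stage); warped(x) = moving(x + u(x)). Voxels whose warped position falls
// outside the moving support are excluded from the metric.
// [[Rcpp::export]]
List cpp_bspline_mse_grad(NumericVector fixed, NumericVector moving,
                          IntegerVector shape, NumericVector origin,
                          NumericVector spacing, NumericVector coef,
                          IntegerVector cshape, NumericVector corigin,
                          NumericVector cspacing, LogicalVector valid) {
  int ncx = cshape[0], ncy = cshape[1], ncz = cshape[2];
  int nx = shape[0], ny = shape[1], nz = shape[2];
  size_t nc = (size_t)ncx * ncy * ncz;
  const double* f = REAL(fixed);
  const double* m = REAL(moving);
  const double* c = REAL(coef);
  NumericVector grad((R_xlen_t)(nc * 3));
  double* g = REAL(grad);
  std::vector<int> ix(nx), iy(ny), iz(nz);
  std::vector<double> wx(nx * 4), wy(ny * 4), wz(nz * 4);
  for (int i = 0; i < nx; i++) {
    double t = (origin[0] + i * spacing[0] - corigin[0]) / cspacing[0];
    int i0 = (int)std::floor(t); ix[i] = i0; bspl_w(t - i0, &wx[i * 4]);
  }
  for (int j = 0; j < ny; j++) {
    double t = (origin[1] + j * spacing[1] - corigin[1]) / cspacing[1];
    int j0 = (int)std::floor(t); iy[j] = j0; bspl_w(t - j0, &wy[j * 4]);
  }
  for (int k = 0; k < nz; k++) {
    double t = (origin[2] + k * spacing[2] - corigin[2]) / cspacing[2];
    int k0 = (int)std::floor(t); iz[k] = k0; bspl_w(t - k0, &wz[k * 4]);
  }
  const int* vld = LOGICAL(valid);
  bool use_valid = valid.size() == (R_xlen_t)((size_t)nx * ny * nz);
  double sse = 0; size_t nin = 0;
  double eps = 0.5; // half-voxel step (index units) for the image gradient
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        if (use_valid && !vld[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)])
          continue;
        double u[3] = {0, 0, 0};
        for (int c3 = 0; c3 < 4; c3++) {
          int kk = iz[k] - 1 + c3; if (kk < 0 || kk >= ncz) continue;
          for (int c2 = 0; c2 < 4; c2++) {
            int jj = iy[j] - 1 + c2; if (jj < 0 || jj >= ncy) continue;
            double wyz = wy[j * 4 + c2] * wz[k * 4 + c3];
            for (int c1 = 0; c1 < 4; c1++) {
              int ii = ix[i] - 1 + c1; if (ii < 0 || ii >= ncx) continue;
              double w = wx[i * 4 + c1] * wyz;
              size_t ci = (size_t)ii + (size_t)ncx * ((size_t)jj + (size_t)ncy * kk);
              u[0] += w * c[ci]; u[1] += w * c[ci + nc]; u[2] += w * c[ci + 2 * nc];
            }
          }
        }
        double gx = i + u[0] / spacing[0];
        double gy = j + u[1] / spacing[1];
        double gz = k + u[2] / spacing[2];
        if (gx < 0 || gy < 0 || gz < 0 || gx > nx - 1 || gy > ny - 1 || gz > nz - 1)
          continue;
        double mv = sample_tri(m, nx, ny, nz, gx, gy, gz, 0.0);
        double fv = f[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
        double r = mv - fv;
        sse += r * r; nin++;
        // image gradient of moving at warped point, per mm
        double dmx = (sample_tri(m, nx, ny, nz, std::min(gx + eps, nx - 1.0), gy, gz, mv) -
                      sample_tri(m, nx, ny, nz, std::max(gx - eps, 0.0), gy, gz, mv)) /
                     (2 * eps * spacing[0]);
        double dmy = (sample_tri(m, nx, ny, nz, gx, std::min(gy + eps, ny - 1.0), gz, mv) -
                      sample_tri(m, nx, ny, nz, gx, std::max(gy - eps, 0.0), gz, mv)) /
                     (2 * eps * spacing[1]);
        double dmz = (sample_tri(m, nx, ny, nz, gx, gy, std::min(gz + eps, nz - 1.0), mv) -
                      sample_tri(m, nx, ny, nz, gx, gy, std::max(gz - eps, 0.0), mv)) /
                     (2 * eps * spacing[2]);
        double f0 = 2 * r * dmx, f1 = 2 * r * dmy, f2 = 2 * r * dmz;
        for (int c3 = 0; c3 < 4; c3++) {
          int kk = iz[k] - 1 + c3; if (kk < 0 || kk >= ncz) continue;
          for (int c2 = 0; c2 < 4; c2++) {
            int jj = iy[j] - 1 + c2; if (jj < 0 || jj >= ncy) continue;
            double wyz = wy[j * 4 + c2] * wz[k * 4 + c3];
            for (int c1 = 0; c1 < 4; c1++) {
              int ii = ix[i] - 1 + c1; if (ii < 0 || ii >= ncx) continue;
              double w = wx[i * 4 + c1] * wyz;
              size_t ci = (size_t)ii + (size_t)ncx * ((size_t)jj + (size_t)ncy * kk);
              g[ci] += w * f0; g[ci + nc] += w * f1; g[ci + 2 * nc] += w * f2;
            }
          }
        }
      }
  if (nin > 0) {
    for (size_t q = 0; q < nc * 3; q++) g[q] /= (double)nin;
    sse /= (double)nin;
  }
  grad.attr("dim") = IntegerVector::create(ncx, ncy, ncz, 3);
  return List::create(_["mse"] = sse, _["grad"] = grad, _["n_inside"] = (double)nin);
}

// MSE and gradient for a centered affine transform p(x) = A (x - ctr) + ctr + t.
// params: 12-vector (A row-major 9, then t 3). fixed and moving may live on
// different grids.
// [[Rcpp::export]]
List cpp_affine_mse_grad(NumericVector fixed, IntegerVector fshape,
                         NumericVector forigin, NumericVector fspacing,
                         NumericVector moving, IntegerVector mshape,
                         NumericVector morigin, NumericVector mspacing,
                         NumericVector params, NumericVector ctr) {
  int fnx = fshape[0], fny = fshape[1], fnz = fshape[2];
  int mnx = mshape[0], mny = mshape[1], mnz = mshape[2];
  const double* f = REAL(fixed);
  const double* m = REAL(moving);
  const double* p = REAL(params);
  NumericVector grad(12);
  double* g = REAL(grad);
  double sse = 0; size_t nin = 0;
  double eps = 0.5;
  for (int k = 0; k < fnz; k++)
    for (int j = 0; j < fny; j++)
      for (int i = 0; i < fnx; i++) {
        double x0 = forigin[0] + i * fspacing[0] - ctr[0];
        double x1 = forigin[1] + j * fspacing[1] - ctr[1];
        double x2 = forigin[2] + k * fspacing[2] - ctr[2];
        double q0 = p[0] * x0 + p[1] * x1 + p[2] * x2 + ctr[0] + p[9];
        double q1 = p[3] * x0 + p[4] * x1 + p[5] * x2 + ctr[1] + p[10];
        double q2 = p[6] * x0 + p[7] * x1 + p[8] * x2 + ctr[2] + p[11];
        double gx = (q0 - morigin[0]) / mspacing[0];
        double gy = (q1 - morigin[1]) / mspacing[1];
        double gz = (q2 - morigin[2]) / mspacing[2];
        if (gx < 0 || gy < 0 || gz < 0 || gx > mnx - 1 || gy > mny - 1 || gz > mnz - 1)
          continue;
        double mv = sample_tri(m, mnx, mny, mnz, gx, gy, gz, 0.0);
        double fv = f[(size_t)i + (size_t)fnx * ((size_t)j + (size_t)fny * k)];
        double r = mv - fv;
        sse += r * r; nin++;
        double dmx = (sample_tri(m, mnx, mny, mnz, std::min(gx + eps, mnx - 1.0), gy, gz, mv) -
                      sample_tri(m, mnx, mny, mnz, std::max(gx - eps, 0.0), gy, gz, mv)) /
                     (2 * eps * mspacing[0]);
        double dmy = (sample_tri(m, mnx, mny, mnz, gx, std::min(gy + eps, mny - 1.0), gz, mv) -
                      sample_tri(m, mnx, mny, mnz, gx, std::max(gy - eps, 0.0), gz, mv)) /
                     (2 * eps * mspacing[1]);
        double dmz = (sample_tri(m, mnx, mny, mnz, gx, gy, std::min(gz + eps, mnz - 1.0), mv) -
                      sample_tri(m, mnx, mny, mnz, gx, gy, std::max(gz - eps, 0.0), mv)) /
                     (2 * eps * mspacing[2]);
        double r2 = 2 * r;
        g[0] += r2 * dmx * x0; g[1] += r2 * dmx * x1; g[2] += r2 * dmx * x2;
        g[3] += r2 * dmy * x0; g[4] += r2 * dmy * x1; g[5] += r2 * dmy * x2;
        g[6] += r2 * dmz * x0; g[7] += r2 * dmz * x1; g[8] += r2 * dmz * x2;
        g[9] += r2 * dmx; g[10] += r2 * dmy; g[11] += r2 * dmz;
      }
  if (nin > 0) {
    for (int q = 0; q < 12; q++) g[q] /= (double)nin;
    sse /= (double)nin;
  }
  return List::create(_["mse"] = sse, _["grad"] = grad, _["n_inside"] = (double)nin);
}
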