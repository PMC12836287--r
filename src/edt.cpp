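#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// 1D squared distance transform of a sampled function (Felzenszwalb &
// Huttenlocher 2012), with sample step `h` (mm). f and d length n.
static void dt1d(const double* f, double* d, int n, double h,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double qq = (double)q * h;
    double s;
    while (true) {
      double vv = (double)v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double qq = (double)q * h;
    while (z[k + 1] < qq) k++;
    double vv = (double)v[k] * h;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Euclidean distance (mm) from every voxel to the nearest `true` voxel of a
// binary mask, honouring anisotropic spacing. Empty mask -> all Inf.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector shape, NumericVector spacing) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  size_t nv = (size_t)nx * ny * nz;
  const double large = 1e20; // finite stand-in for +Inf; keeps dt1d's
                             // intersection arithmetic well-defined
  NumericVector out((R_xlen_t)nv);
  double* d = REAL(out);
  const int* msk = LOGICAL(mask);
  for (size_t i = 0; i < nv; i++) d[i] = msk[i] ? 0.0 : large;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
#define IDX(i, j, k) ((size_t)(i) + (size_t)nx * ((size_t)(j) + (size_t)ny * (size_t)(k)))
  // along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      for (int i = 0; i < nx; i++) f[i] = d[IDX(i, j, k)];
      dt1d(f.data(), dd.data(), nx, spacing[0], v, z);
      for (int i = 0; i < nx; i++) d[IDX(i, j, k)] = dd[i];
    }
  // along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      for (int j = 0; j < ny; j++) f[j] = d[IDX(i, j, k)];
      dt1d(f.data(), dd.data(), ny, spacing[1], v, z);
      for (int j = 0; j < ny; j++) d[IDX(i, j, k)] = dd[j];
    }
  // along z
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      for (int k = 0; k < nz; k++) f[k] = d[IDX(i, j, k)];
      dt1d(f.data(), dd.data(), nz, spacing[2], v, z);
      for (int k = 0; k < nz; k++) d[IDX(i, j, k)] = dd[k];
    }
#undef IDX
  for (size_t i = 0; i < nv; i++)
    d[i] = d[i] >= 1e19 ? R_PosInf : std::sqrt(d[i]);
  out.attr("dim") = shape;
  return out;
}
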