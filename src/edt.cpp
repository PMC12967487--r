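#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// One-dimensional squared Euclidean distance transform along a line of n
// samples spaced w apart (Felzenszwalb & Huttenlocher lower envelope of
// parabolas). f holds squared distances on input; d receives the result.
// Parabolas with f == INF (no feature reachable yet) are skipped.
static void dt1d(const double* f, double* d, int n, double w,
                 std::vector<int>& v, std::vector<double>& z) {
  const double w2 = w * w;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (k >= 0) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
          (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; }
    else { ++k; v[k] = q; z[k] = s; z[k + 1] = INF; }
  }
  if (k < 0) { // no features on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    int p = v[j];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// Exact anisotropic squared EDT of a 3-D binary feature image: result at each
// voxel is the squared physical distance (spacing in mm per axis) from its
// center to the nearest feature voxel center, Inf if there are no features.
// [[Rcpp::export]]
NumericVector edt_squared_cpp(LogicalVector feature, IntegerVector dim,
                              NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (feature.size() != n) stop("feature length does not match dim");
  NumericVector out(n);
  double* D = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i)
    D[i] = (feature[i] == TRUE) ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky) {
      double* line = D + (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
      dt1d(line, f.data(), nx, spacing[0], v, z);
      std::copy(f.begin(), f.begin() + nx, line);
    }
  // pass along y
  for (int kz = 0; kz < nz; ++kz)
    for (int kx = 0; kx < nx; ++kx) {
      double* base = D + (R_xlen_t)kz * nx * ny + kx;
      for (int ky = 0; ky < ny; ++ky) f[ky] = base[(R_xlen_t)ky * nx];
      dt1d(f.data(), d.data(), ny, spacing[1], v, z);
      for (int ky = 0; ky < ny; ++ky) base[(R_xlen_t)ky * nx] = d[ky];
    }
  // pass along z
  const R_xlen_t slice = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ++ky)
    for (int kx = 0; kx < nx; ++kx) {
      double* base = D + (R_xlen_t)ky * nx + kx;
      for (int kz = 0; kz < nz; ++kz) f[kz] = base[kz * slice];
      dt1d(f.data(), d.data(), nz, spacing[2], v, z);
      for (int kz = 0; kz < nz; ++kz) base[kz * slice] = d[kz];
    }
  return out;
}
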