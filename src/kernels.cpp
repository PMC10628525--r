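#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// 1D squared Euclidean distance transform (Felzenszwalb & Huttenlocher 2012)
// for samples at physical positions i*step. f holds squared distances on
// input; result written back into f.
static void dt1d(std::vector<double>& f, int n, double step,
                 std::vector<int>& v, std::vector<double>& z,
                 std::vector<double>& d) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qs = q * step;
    double s;
    while (true) {
      double vs = v[k] * step;
      s = ((f[q] + qs * qs) - (f[v[k]] + vs * vs)) / (2.0 * (qs - vs));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * step;
    while (z[k + 1] < qs) ++k;
    double diff = qs - v[k] * step;
    d[q] = diff * diff + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact spacing-aware squared Euclidean distance transform of a 3D binary
// mask: each voxel's squared distance (mm^2) to the nearest voxel centre
// with mask != 0. In-mask voxels get 0.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(IntegerVector mask, IntegerVector dims,
                         NumericVector spacing) {
  // large finite stand-in for +inf keeps the envelope arithmetic NaN-free
  const double BIG = 1e30;
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] != 0 ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, nx, spacing[0], v, z, d);
      for (int i = 0; i < nx; ++i) out[base + i] = f[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, ny, spacing[1], v, z, d);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = f[j];
    }
  // pass along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nxy];
      dt1d(f, nz, spacing[2], v, z, d);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nxy] = f[k];
    }
  return out;
}

// Symmetric GLCM counts for one offset. levels: quantized volume
// (1..n_levels, 0 = outside ROI); both ends of a pair must be in the ROI.
// Pair (a,b) increments (a,b) and (b,a).
// [[Rcpp::export(name = ".glcm_counts_cpp")]]
NumericMatrix glcm_counts_cpp(IntegerVector levels, IntegerVector dims,
                              IntegerVector offset, int n_levels) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int dx = offset[0], dy = offset[1], dz = offset[2];
  NumericMatrix P(n_levels, n_levels);
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  int i0 = std::max(0, -dx), i1 = std::min(nx, nx - dx);
  int j0 = std::max(0, -dy), j1 = std::min(ny, ny - dy);
  int k0 = std::max(0, -dz), k1 = std::min(nz, nz - dz);
  for (int k = k0; k < k1; ++k)
    for (int j = j0; j < j1; ++j) {
      R_xlen_t base = (R_xlen_t)k * nxy + (R_xlen_t)j * nx;
      R_xlen_t obase = (R_xlen_t)(k + dz) * nxy + (R_xlen_t)(j + dy) * nx + dx;
      for (int i = i0; i < i1; ++i) {
        int a = levels[base + i];
        if (a == 0) continue;
        int b = levels[obase + i];
        if (b == 0) continue;
        P(a - 1, b - 1) += 1.0;
        P(b - 1, a - 1) += 1.0;
      }
    }
  return P;
}
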