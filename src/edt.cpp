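#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1-D squared-distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher.  f: input squared distances, w: sample
// spacing along this axis.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double w) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * w;
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (mm) from every voxel to the nearest background
// (zero) voxel, with anisotropic spacing.  Voxels beyond the array
// border count as background at one-spacing distance.
// [[Rcpp::export]]
NumericVector edt3d(LogicalVector inside, IntegerVector dim,
                    NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // large finite stand-in for +inf keeps the parabola intersections finite
  const double BIG = 1e20;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = inside[i] ? BIG : 0.0;

  std::vector<double> f, d;

  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, spacing[0]);
      for (int x = 0; x < nx; ++x) {
        // border behaves as background one step outside
        double b = spacing[0] * (std::min(x, nx - 1 - x) + 1);
        out[base + x] = std::min(d[x], b * b);
      }
    }

  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, spacing[1]);
      for (int y = 0; y < ny; ++y) {
        double b = spacing[1] * (std::min(y, ny - 1 - y) + 1);
        out[base + (R_xlen_t)y * nx] = std::min(d[y], b * b);
      }
    }

  // pass along z
  f.resize(nz); d.resize(nz);
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * sz];
      dt1d(f, d, spacing[2]);
      for (int z = 0; z < nz; ++z) {
        double b = spacing[2] * (std::min(z, nz - 1 - z) + 1);
        out[base + (R_xlen_t)z * sz] = std::min(d[z], b * b);
      }
    }

  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}
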