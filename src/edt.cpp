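#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher exact 1-D squared distance transform on a
// sampled grid with physical spacing h (lower envelope of parabolas).
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double h, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * h;
    while (z[k + 1] < xq) ++k;
    const double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// Anisotropic Euclidean distance transform: distance (mm) from each
// foreground voxel center to the nearest background voxel center.
// [[Rcpp::export(name = ".cpp_edt")]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e20;
  std::vector<double> g((size_t)nx * ny * nz);
  for (size_t i = 0; i < g.size(); ++i) g[i] = mask[i] ? INF : 0.0;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const size_t base = ((size_t)k * ny + j) * nx;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, spacing[0], nx);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const size_t base = (size_t)k * ny * nx + i;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (size_t)j * nx];
      dt1d(f, d, spacing[1], ny);
      for (int j = 0; j < ny; ++j) g[base + (size_t)j * nx] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const size_t base = (size_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = g[base + (size_t)k * ny * nx];
      dt1d(f, d, spacing[2], nz);
      for (int k = 0; k < nz; ++k) g[base + (size_t)k * ny * nx] = d[k];
    }

  NumericVector out((R_xlen_t)nx * ny * nz);
  for (size_t i = 0; i < g.size(); ++i) out[i] = std::sqrt(g[i]);
  return out;
}
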