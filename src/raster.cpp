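#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Rasterize a set of tubes into a supersampled grid and average down.
// Each tube is given as densely resampled centerline points with per-point
// radius and signal value; a subvoxel is foreground if it lies within the
// local radius of any centerline sample (union-of-spheres model, sample
// step << subvoxel size so the union is indistinguishable from the tube).
// Overlapping vessels combine by maximum, like flow-compensated TOF signal.
// [[Rcpp::export(name = ".cpp_raster_tubes")]]
NumericVector cpp_raster_tubes(IntegerVector dims, NumericVector spacing,
                               NumericVector origin, int supersample,
                               List tubes) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int s = supersample;
  const long snx = (long)nx * s, sny = (long)ny * s, snz = (long)nz * s;
  const double hx = spacing[0] / s, hy = spacing[1] / s, hz = spacing[2] / s;
  // subvoxel center q (0-based): origin + (q + 0.5) * h
  std::vector<float> buf((size_t)snx * sny * snz, 0.0f);

  for (int t = 0; t < tubes.size(); ++t) {
    List tube = tubes[t];
    NumericMatrix P = tube["points"];   // n x 3, world mm
    NumericVector R = tube["radius"];   // n
    NumericVector V = tube["value"];    // n
    const int n = P.nrow();
    for (int k = 0; k < n; ++k) {
      const double cx = P(k, 0), cy = P(k, 1), cz = P(k, 2);
      const double r = R[k], r2 = r * r;
      const float v = (float)V[k];
      int i0 = (int)std::floor((cx - r - origin[0]) / hx - 0.5);
      int i1 = (int)std::ceil((cx + r - origin[0]) / hx - 0.5);
      int j0 = (int)std::floor((cy - r - origin[1]) / hy - 0.5);
      int j1 = (int)std::ceil((cy + r - origin[1]) / hy - 0.5);
      int k0 = (int)std::floor((cz - r - origin[2]) / hz - 0.5);
      int k1 = (int)std::ceil((cz + r - origin[2]) / hz - 0.5);
      if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
      if (i1 >= snx) i1 = snx - 1;
      if (j1 >= sny) j1 = sny - 1;
      if (k1 >= snz) k1 = snz - 1;
      for (int kk = k0; kk <= k1; ++kk) {
        const double dz = origin[2] + (kk + 0.5) * hz - cz;
        const double dz2 = dz * dz;
        if (dz2 > r2) continue;
        for (int jj = j0; jj <= j1; ++jj) {
          const double dy = origin[1] + (jj + 0.5) * hy - cy;
          const double dyz2 = dy * dy + dz2;
          if (dyz2 > r2) continue;
          const size_t base = ((size_t)kk * sny + jj) * snx;
          for (int ii = i0; ii <= i1; ++ii) {
            const double dx = origin[0] + (ii + 0.5) * hx - cx;
            if (dx * dx + dyz2 <= r2) {
              float &cell = buf[base + ii];
              if (v > cell) cell = v;
            }
          }
        }
      }
    }
  }

  // average s^3 subvoxels down to each output voxel
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double inv = 1.0 / ((double)s * s * s);
  for (int kk = 0; kk < nz; ++kk)
    for (int jj = 0; jj < ny; ++jj)
      for (int ii = 0; ii < nx; ++ii) {
        double acc = 0.0;
        for (int c = 0; c < s; ++c) {
          const size_t zb = (size_t)(kk * s + c) * sny;
          for (int b = 0; b < s; ++b) {
            const size_t yb = (zb + jj * s + b) * snx + ii * s;
            for (int a = 0; a < s; ++a) acc += buf[yb + a];
          }
        }
        out[((R_xlen_t)kk * ny + jj) * nx + ii] = acc * inv;
      }
  return out;
}
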