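#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D topology-preserving thinning to a one-voxel-thick curve skeleton.
// Sequential border peeling over the six face directions; a voxel may be
// deleted only if it is a simple point (deletion preserves both the
// 26-connectivity of the foreground and the 6-connectivity of the
// background), is not a curve endpoint, and is not in the preserve set.
//
// Simple-point characterization (Bertrand & Malandain):
//   (a) exactly one 26-connected foreground component in the 26-neighborhood
//   (b) exactly one 6-connected background component in the 18-neighborhood
//       that is 6-adjacent to the center

namespace {

struct Cube {
  // local 3x3x3 neighborhood, index = (dz+1)*9 + (dy+1)*3 + (dx+1)
  bool fg[27];
};

inline int lidx(int dx, int dy, int dz) {
  return (dz + 1) * 9 + (dy + 1) * 3 + (dx + 1);
}

// 26-connected components of foreground among the 26 neighbors (center
// excluded); returns the number of components.
int n_fg_components(const Cube &c) {
  int label[27];
  for (int i = 0; i < 27; ++i) label[i] = 0;
  int ncomp = 0;
  int stack[27];
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !c.fg[i] || label[i]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = i;
    label[i] = ncomp;
    while (top) {
      const int p = stack[--top];
      const int pz = p / 9, py = (p % 9) / 3, px = p % 3;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            const int qz = pz + dz, qy = py + dy, qx = px + dx;
            if (qz < 0 || qz > 2 || qy < 0 || qy > 2 || qx < 0 || qx > 2)
              continue;
            const int q = qz * 9 + qy * 3 + qx;
            if (q == 13 || q == p || !c.fg[q] || label[q]) continue;
            label[q] = ncomp;
            stack[top++] = q;
          }
    }
  }
  return ncomp;
}

// 6-connected components of background within the 18-neighborhood that
// touch the center by a face; 6-connectivity paths restricted to N18.
int n_bg_components(const Cube &c) {
  static const int face[6] = {lidx(-1, 0, 0), lidx(1, 0, 0), lidx(0, -1, 0),
                              lidx(0, 1, 0),  lidx(0, 0, -1), lidx(0, 0, 1)};
  bool in18[27];
  for (int z = 0; z < 3; ++z)
    for (int y = 0; y < 3; ++y)
      for (int x = 0; x < 3; ++x) {
        const int manh = (x != 1) + (y != 1) + (z != 1);
        in18[z * 9 + y * 3 + x] = (manh >= 1 && manh <= 2);
      }
  int label[27];
  for (int i = 0; i < 27; ++i) label[i] = 0;
  int ncomp = 0;
  int stack[27];
  for (int f = 0; f < 6; ++f) {
    const int i = face[f];
    if (c.fg[i] || label[i]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = i;
    label[i] = ncomp;
    while (top) {
      const int p = stack[--top];
      const int pz = p / 9, py = (p % 9) / 3, px = p % 3;
      static const int d6[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                                   {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
      for (int d = 0; d < 6; ++d) {
        const int qz = pz + d6[d][2], qy = py + d6[d][1], qx = px + d6[d][0];
        if (qz < 0 || qz > 2 || qy < 0 || qy > 2 || qx < 0 || qx > 2) continue;
        const int q = qz * 9 + qy * 3 + qx;
        if (!in18[q] || c.fg[q] || label[q]) continue;
        label[q] = ncomp;
        stack[top++] = q;
      }
    }
  }
  return ncomp;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_thin3d")]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims,
                         LogicalVector preserve) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<unsigned char> m(n);
  for (size_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;
  const bool has_pres = preserve.size() == (R_xlen_t)n;

  auto at = [&](int x, int y, int z) -> unsigned char {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
    return m[(size_t)z * ny * nx + (size_t)y * nx + x];
  };

  static const int dir[6][3] = {{0, 0, 1},  {0, 0, -1}, {0, 1, 0},
                                {0, -1, 0}, {1, 0, 0},  {-1, 0, 0}};

  // candidate list per subiteration: border voxels in the given direction
  std::vector<size_t> cand;
  bool any_deleted = true;
  while (any_deleted) {
    any_deleted = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            const size_t p = (size_t)z * ny * nx + (size_t)y * nx + x;
            if (!m[p]) continue;
            if (has_pres && preserve[p]) continue;
            if (at(x + dir[d][0], y + dir[d][1], z + dir[d][2])) continue;
            cand.push_back(p);
          }
      // sequential re-check and delete
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        const size_t p = cand[ci];
        if (!m[p]) continue;
        const int x = (int)(p % nx);
        const int y = (int)((p / nx) % ny);
        const int z = (int)(p / ((size_t)nx * ny));
        Cube c;
        int nn = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              const bool fg = at(x + dx, y + dy, z + dz) != 0;
              c.fg[lidx(dx, dy, dz)] = fg;
              if (fg && !(dx == 0 && dy == 0 && dz == 0)) ++nn;
            }
        if (nn <= 1) continue;  // endpoint or isolated: keep
        if (n_fg_components(c) != 1) continue;
        if (n_bg_components(c) != 1) continue;
        m[p] = 0;
        any_deleted = true;
      }
    }
  }

  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  return out;
}
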