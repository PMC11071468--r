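#ifndef VOXSEG_LATTICE_H
#define VOXSEG_LATTICE_H

#include <Rcpp.h>
#include <vector>

// Linear voxel index: v = x + nx * (y + ny * z), all 0-based.
struct Grid {
  int nx, ny, nz;
  Grid(int nx_, int ny_, int nz_) : nx(nx_), ny(ny_), nz(nz_) {}
  inline int n() const { return nx * ny * nz; }
  inline int idx(int x, int y, int z) const { return x + nx * (y + ny * z); }
  inline void coords(int v, int &x, int &y, int &z) const {
    x = v % nx; int r = v / nx; y = r % ny; z = r / ny;
  }
  inline bool inb(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
  // von Neumann (6-) neighbors; returns count, fills buf
  inline int vn_neighbors(int v, int *buf) const {
    int x, y, z, k = 0;
    coords(v, x, y, z);
    if (x > 0) buf[k++] = idx(x - 1, y, z);
    if (x < nx - 1) buf[k++] = idx(x + 1, y, z);
    if (y > 0) buf[k++] = idx(x, y - 1, z);
    if (y < ny - 1) buf[k++] = idx(x, y + 1, z);
    if (z > 0) buf[k++] = idx(x, y, z - 1);
    if (z < nz - 1) buf[k++] = idx(x, y, z + 1);
    return k;
  }
  // Moore (26-) neighbors
  inline int moore_neighbors(int v, int *buf) const {
    int x, y, z, k = 0;
    coords(v, x, y, z);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          if (inb(x + dx, y + dy, z + dz)) buf[k++] = idx(x + dx, y + dy, z + dz);
        }
    return k;
  }
  // in-plane Moore (8-) neighbors, same z-layer
  inline int inplane_neighbors(int v, int *buf) const {
    int x, y, z, k = 0;
    coords(v, x, y, z);
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0) continue;
        if (inb(x + dx, y + dy, z)) buf[k++] = idx(x + dx, y + dy, z);
      }
    return k;
  }
};

// Does changing the state of voxel j alter the number of Moore-connected
// components of {voxels with state == label} within Moore(j) + j?
// `has_j` is whether j currently counts as `label`.
bool local_articulation(const int *state, const Grid &g, int j, int label);

#endif
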