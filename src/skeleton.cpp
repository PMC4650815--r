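// Topology-preserving 3D thinning.
//
// Sequential border thinning over six directional subcycles. A foreground
// voxel is deletable when it is a border point in the current direction,
// still has at least three foreground 26-neighbors (one-voxel-thick curve
// voxels are frozen) and is a simple point in the sense of Malandain &
// Bertrand: exactly one 26-connected foreground component in its
// 26-neighborhood, and exactly one 6-connected background component of its
// 18-neighborhood that is 6-adjacent to the voxel. Deleting only simple
// points guarantees that connected components, holes and cavities (hence
// the Euler characteristic) of the object are preserved; sequential
// (re-checked) deletion keeps the guarantee within each subcycle.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

namespace {

int off26[26][3];
// adjacency tables over the 27-cell cube (index = (dx+1)+3*(dy+1)+9*(dz+1))
std::vector<int> adj26[27];   // 26-adjacency among the 26 non-center cells
std::vector<int> adj6_18[27]; // 6-adjacency among the 18-neighborhood cells
bool is18[27];
bool is6[27];
bool tables_ready = false;

void build_tables() {
  if (tables_ready) return;
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx || dy || dz) {
          off26[k][0] = dx; off26[k][1] = dy; off26[k][2] = dz; ++k;
        }
      }
  for (int i = 0; i < 27; ++i) {
    const int ix = i % 3 - 1, iy = (i / 3) % 3 - 1, iz = i / 9 - 1;
    const int s = abs(ix) + abs(iy) + abs(iz);
    is18[i] = (s >= 1 && s <= 2);
    is6[i] = (s == 1);
  }
  for (int i = 0; i < 27; ++i) {
    const int ix = i % 3 - 1, iy = (i / 3) % 3 - 1, iz = i / 9 - 1;
    for (int j = 0; j < 27; ++j) {
      if (i == j) continue;
      const int jx = j % 3 - 1, jy = (j / 3) % 3 - 1, jz = j / 9 - 1;
      const int ax = abs(ix - jx), ay = abs(iy - jy), az = abs(iz - jz);
      const bool center_i = (ix == 0 && iy == 0 && iz == 0);
      const bool center_j = (jx == 0 && jy == 0 && jz == 0);
      if (!center_i && !center_j && ax <= 1 && ay <= 1 && az <= 1)
        adj26[i].push_back(j);
      if (is18[i] && is18[j] && ax + ay + az == 1)
        adj6_18[i].push_back(j);
    }
  }
  tables_ready = true;
}

struct Grid {
  const std::vector<uint8_t> *fg;
  int nx, ny, nz;
  bool at(int x, int y, int z) const {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return false;
    return (*fg)[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] != 0;
  }
};

int count_nbr26(const Grid &g, int x, int y, int z) {
  int c = 0;
  for (int t = 0; t < 26; ++t)
    if (g.at(x + off26[t][0], y + off26[t][1], z + off26[t][2])) ++c;
  return c;
}

bool is_simple(const Grid &g, int x, int y, int z) {
  bool cube[27];
  for (int i = 0; i < 27; ++i) {
    const int ix = i % 3 - 1, iy = (i / 3) % 3 - 1, iz = i / 9 - 1;
    cube[i] = g.at(x + ix, y + iy, z + iz);
  }
  // condition A: one 26-component of foreground among the 26 neighbors
  {
    int comp = 0;
    bool seen[27] = { false };
    for (int i = 0; i < 27; ++i) {
      if (i == 13 || !cube[i] || seen[i]) continue;
      if (++comp > 1) return false;
      int stack[26], sp = 0;
      stack[sp++] = i; seen[i] = true;
      while (sp) {
        const int c = stack[--sp];
        for (int j : adj26[c]) {
          if (j == 13 || !cube[j] || seen[j]) continue;
          seen[j] = true; stack[sp++] = j;
        }
      }
    }
    if (comp != 1) return false;
  }
  // condition B: one 6-component of background in the 18-neighborhood that
  // is 6-adjacent to the center
  {
    int comp = 0;
    bool seen[27] = { false };
    for (int i = 0; i < 27; ++i) {
      if (!is18[i] || cube[i] || seen[i]) continue;
      // flood this background component within the 18-neighborhood
      int stack[18], sp = 0;
      stack[sp++] = i; seen[i] = true;
      bool touches = is6[i];
      while (sp) {
        const int c = stack[--sp];
        for (int j : adj6_18[c]) {
          if (cube[j] || seen[j]) continue;
          seen[j] = true;
          if (is6[j]) touches = true;
          stack[sp++] = j;
        }
      }
      if (touches && ++comp > 1) return false;
    }
    if (comp != 1) return false;
  }
  return true;
}

} // namespace

// Border thinning over six directional subcycles (U, D, N, S, E, W).
// Candidates of each subcycle are collected up front (voxels whose
// neighbor in the current direction is background), then deleted
// sequentially with re-checking, so deletion within a subcycle cannot
// cascade along a vessel. A voxel is deleted only when it is a simple
// point (topology preserved) AND still has at least three foreground
// 26-neighbors: voxels that are already part of a one-voxel-thick curve
// (<= 2 neighbors) are frozen, which preserves curve length and keeps
// closed loops from contracting homotopically.
// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dim) {
  build_tables();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = mask.size();
  std::vector<uint8_t> fg(n, 0);
  std::vector<R_xlen_t> active;
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) { fg[i] = 1; active.push_back(i); }
  Grid g{ &fg, nx, ny, nz };

  const int dirs[6][3] = { {0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0} };
  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (R_xlen_t i : active) {
        if (!fg[i]) continue;
        const int x = (int)(i % nx);
        const int y = (int)((i / nx) % ny);
        const int z = (int)(i / ((R_xlen_t)nx * ny));
        if (g.at(x + dirs[d][0], y + dirs[d][1], z + dirs[d][2])) continue;
        if (count_nbr26(g, x, y, z) <= 2) continue;  // frozen curve voxel
        if (is_simple(g, x, y, z)) cand.push_back(i);
      }
      for (R_xlen_t i : cand) {
        const int x = (int)(i % nx);
        const int y = (int)((i / nx) % ny);
        const int z = (int)(i / ((R_xlen_t)nx * ny));
        // re-check under the current (partially thinned) object
        if (count_nbr26(g, x, y, z) <= 2) continue;
        if (!is_simple(g, x, y, z)) continue;
        fg[i] = 0;
        changed = true;
      }
    }
    R_xlen_t keep = 0;
    for (R_xlen_t i : active) if (fg[i]) active[keep++] = i;
    active.resize(keep);
  }
  // Cleanup: remove redundant corner voxels -- curve voxels whose exactly
  // two neighbors are themselves 26-adjacent (the curve passes without
  // them). This dissolves frozen 3-voxel micro-triangles left by the
  // freeze rule; each deletion is a simple-point deletion, so topology of
  // anything larger is untouched.
  changed = true;
  while (changed) {
    changed = false;
    for (R_xlen_t i : active) {
      if (!fg[i]) continue;
      const int x = (int)(i % nx);
      const int y = (int)((i / nx) % ny);
      const int z = (int)(i / ((R_xlen_t)nx * ny));
      int nb[2], cnt = 0;
      bool two = true;
      for (int t = 0; t < 26 && two; ++t) {
        const int xx = x + off26[t][0], yy = y + off26[t][1],
                  zz = z + off26[t][2];
        if (g.at(xx, yy, zz)) {
          if (cnt < 2) nb[cnt] = t;
          if (++cnt > 2) two = false;
        }
      }
      if (!two || cnt != 2) continue;
      const int dx = off26[nb[0]][0] - off26[nb[1]][0];
      const int dy = off26[nb[0]][1] - off26[nb[1]][1];
      const int dz = off26[nb[0]][2] - off26[nb[1]][2];
      if (abs(dx) > 1 || abs(dy) > 1 || abs(dz) > 1) continue;  // not adjacent
      if (!is_simple(g, x, y, z)) continue;
      fg[i] = 0;
      changed = true;
    }
    R_xlen_t keep = 0;
    for (R_xlen_t i : active) if (fg[i]) active[keep++] = i;
    active.resize(keep);
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (fg[i] != 0);
  return out;
}

// Number of foreground 26-neighbors for every voxel of a mask (0 elsewhere).
// [[Rcpp::export]]
IntegerVector cpp_neighbor_count26(LogicalVector mask, IntegerVector dim) {
  build_tables();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = mask.size();
  std::vector<uint8_t> fg(n, 0);
  for (R_xlen_t i = 0; i < n; ++i) fg[i] = mask[i] ? 1 : 0;
  Grid g{ &fg, nx, ny, nz };
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!fg[i]) continue;
    const int x = (int)(i % nx);
    const int y = (int)((i / nx) % ny);
    const int z = (int)(i / ((R_xlen_t)nx * ny));
    out[i] = count_nbr26(g, x, y, z);
  }
  return out;
}
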