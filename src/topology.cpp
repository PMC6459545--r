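#include <Rcpp.h>
#include <vector>
#include <array>
#include <climits>
#include <cstdlib>
using namespace Rcpp;

// Shared helpers for 3D digital topology on column-major (nx, ny, nz) grids.

namespace {

struct Grid {
  const int nx, ny, nz;
  Grid(int x, int y, int z) : nx(x), ny(y), nz(z) {}
  inline bool inside(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
  inline long idx(int x, int y, int z) const {
    return (long)x + (long)nx * ((long)y + (long)ny * z);
  }
};

// Gather the 3x3x3 neighbourhood of p into nb[27] (local index
// lx + 3*ly + 9*lz, centre = 13); voxels outside the volume are background.
inline void gatherNeighbourhood(const std::vector<unsigned char>& vol,
                                const Grid& g, int x, int y, int z,
                                unsigned char nb[27]) {
  int li = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++li) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        nb[li] = g.inside(xx, yy, zz) ? vol[g.idx(xx, yy, zz)] : 0;
      }
}

inline void localCoord(int li, int& lx, int& ly, int& lz) {
  lx = li % 3; ly = (li / 3) % 3; lz = li / 9;
}

// Number of foreground 26-components among the 26 neighbours (centre excluded).
int countFgComponents26(const unsigned char nb[27]) {
  bool visited[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || visited[s]) continue;
    ++comps;
    int stack[27], top = 0;
    stack[top++] = s; visited[s] = true;
    while (top) {
      int c = stack[--top];
      int cx, cy, cz; localCoord(c, cx, cy, cz);
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || visited[t] || !nb[t]) continue;
        int tx, ty, tz; localCoord(t, tx, ty, tz);
        if (std::abs(tx - cx) <= 1 && std::abs(ty - cy) <= 1 &&
            std::abs(tz - cz) <= 1) {
          visited[t] = true; stack[top++] = t;
        }
      }
    }
  }
  return comps;
}

// Number of background 6-components of the 18-neighbourhood that are
// 6-adjacent to the centre (i.e. contain one of the 6 face neighbours).
int countBgComponents6(const unsigned char nb[27]) {
  bool inN18[27];
  for (int t = 0; t < 27; ++t) {
    int tx, ty, tz; localCoord(t, tx, ty, tz);
    int d = std::abs(tx - 1) + std::abs(ty - 1) + std::abs(tz - 1);
    inN18[t] = (d >= 1 && d <= 2);
  }
  static const int faces[6] = {13 - 1, 13 + 1, 13 - 3, 13 + 3, 13 - 9, 13 + 9};
  bool visited[27] = {false};
  int comps = 0;
  for (int f = 0; f < 6; ++f) {
    int s = faces[f];
    if (nb[s] || visited[s]) continue;
    ++comps;
    int stack[27], top = 0;
    stack[top++] = s; visited[s] = true;
    while (top) {
      int c = stack[--top];
      int cx, cy, cz; localCoord(c, cx, cy, cz);
      for (int t = 0; t < 27; ++t) {
        if (!inN18[t] || visited[t] || nb[t]) continue;
        int tx, ty, tz; localCoord(t, tx, ty, tz);
        if (std::abs(tx - cx) + std::abs(ty - cy) + std::abs(tz - cz) == 1) {
          visited[t] = true; stack[top++] = t;
        }
      }
    }
  }
  return comps;
}

inline int countFgNeighbours(const unsigned char nb[27]) {
  int n = 0;
  for (int t = 0; t < 27; ++t) if (t != 13 && nb[t]) ++n;
  return n;
}

// A foreground voxel is simple (deletable without changing topology) iff its
// 26-neighbourhood holds exactly one foreground 26-component and the
// 18-neighbourhood holds exactly one background 6-component adjacent to it.
inline bool isSimple(const unsigned char nb[27]) {
  return countFgComponents26(nb) == 1 && countBgComponents6(nb) == 1;
}

} // namespace

// Curve thinning by iterative deletion of simple border points, six
// directional subiterations per pass, preserving curve endpoints (voxels with
// a single foreground 26-neighbour) and isolated voxels.
// [[Rcpp::export]]
LogicalVector cpp_skeletonize3d(LogicalVector vol, IntegerVector dim) {
  Grid g(dim[0], dim[1], dim[2]);
  const long nvox = (long)g.nx * g.ny * g.nz;
  std::vector<unsigned char> v(nvox);
  for (long i = 0; i < nvox; ++i) v[i] = vol[i] ? 1 : 0;

  static const int dirs[6][3] = {{0, 0, 1},  {0, 0, -1}, {0, 1, 0},
                                 {0, -1, 0}, {1, 0, 0},  {-1, 0, 0}};
  std::vector<long> cand;
  unsigned char nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < g.nz; ++z)
        for (int y = 0; y < g.ny; ++y)
          for (int x = 0; x < g.nx; ++x) {
            long i = g.idx(x, y, z);
            if (!v[i]) continue;
            int bx = x + dirs[d][0], by = y + dirs[d][1], bz = z + dirs[d][2];
            if (g.inside(bx, by, bz) && v[g.idx(bx, by, bz)]) continue;
            gatherNeighbourhood(v, g, x, y, z, nb);
            if (countFgNeighbours(nb) < 2) continue; // endpoint or isolated
            if (isSimple(nb)) cand.push_back(i);
          }
      // sequential deletion with re-check keeps the topology exact
      for (long i : cand) {
        int x = (int)(i % g.nx);
        int y = (int)((i / g.nx) % g.ny);
        int z = (int)(i / ((long)g.nx * g.ny));
        gatherNeighbourhood(v, g, x, y, z, nb);
        if (countFgNeighbours(nb) >= 2 && isSimple(nb)) {
          v[i] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(nvox);
  for (long i = 0; i < nvox; ++i) out[i] = v[i] != 0;
  return out;
}

// Connected-component labelling under 6/18/26 connectivity; labels are
// assigned in scan order of each component's first-encountered voxel.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  Grid g(dim[0], dim[1], dim[2]);
  const long nvox = (long)g.nx * g.ny * g.nz;
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  IntegerVector lab(nvox, 0);
  std::vector<long> stack;
  int next = 0;
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        long i = g.idx(x, y, z);
        if (!mask[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          long c = stack.back(); stack.pop_back();
          int cx = (int)(c % g.nx);
          int cy = (int)((c / g.nx) % g.ny);
          int cz = (int)(c / ((long)g.nx * g.ny));
          for (auto& o : offs) {
            int tx = cx + o[0], ty = cy + o[1], tz = cz + o[2];
            if (!g.inside(tx, ty, tz)) continue;
            long t = g.idx(tx, ty, tz);
            if (mask[t] && !lab[t]) {
              lab[t] = next;
              stack.push_back(t);
            }
          }
        }
      }
  lab.attr("n") = next;
  return lab;
}

// For each query voxel (1-based x,y,z rows) return the label at the voxel or,
// if zero there, the label of the nearest labelled voxel within maxRadius
// (Euclidean tie-break by scan order); 0 if none found.
// [[Rcpp::export]]
IntegerVector cpp_nearest_label(IntegerVector labels, IntegerVector dim,
                                IntegerMatrix coords, int maxRadius) {
  Grid g(dim[0], dim[1], dim[2]);
  const int n = coords.nrow();
  IntegerVector out(n);
  for (int q = 0; q < n; ++q) {
    int x = coords(q, 0) - 1, y = coords(q, 1) - 1, z = coords(q, 2) - 1;
    if (!g.inside(x, y, z)) { out[q] = 0; continue; }
    int best = labels[g.idx(x, y, z)];
    if (best > 0) { out[q] = best; continue; }
    int bestd2 = INT_MAX;
    for (int r = 1; r <= maxRadius && best == 0; ++r) {
      for (int dz = -r; dz <= r; ++dz)
        for (int dy = -r; dy <= r; ++dy)
          for (int dx = -r; dx <= r; ++dx) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r)
              continue; // shell only
            int tx = x + dx, ty = y + dy, tz = z + dz;
            if (!g.inside(tx, ty, tz)) continue;
            int l = labels[g.idx(tx, ty, tz)];
            if (l > 0) {
              int d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < bestd2) { bestd2 = d2; best = l; }
            }
          }
      if (bestd2 < INT_MAX) break;
    }
    out[q] = best;
  }
  return out;
}
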