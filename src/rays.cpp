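#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ray-cast diameter estimation. For each medial-axis point with a known fiber
// direction, march n_rays rays in the plane perpendicular to the direction,
// sampling the binary volume by nearest-voxel lookup, and average the chord
// lengths of opposite-ray pairs.
//
// coords: 1-based voxel coordinates (x,y,z), one row per point.
// dirs:   unit direction vectors, one row per point.
// Returns a matrix with columns:
//   diameter  mean chord over valid pairs (NA if none)
//   n_pairs   number of pairs with both rays terminating in-bounds
//   censored  1 if any contributing ray was stopped at max_march
//   on_fg     1 if the point itself lies on foreground
// [[Rcpp::export]]
NumericMatrix cpp_cast_rays(LogicalVector vol, IntegerVector dim,
                            NumericMatrix coords, NumericMatrix dirs,
                            int nRays, double step, double maxMarch) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = coords.nrow();
  const int half = nRays / 2;
  NumericMatrix out(n, 4);
  colnames(out) = CharacterVector::create("diameter", "n_pairs",
                                          "censored", "on_fg");
  std::vector<double> rdist(nRays), rvalid(nRays), rcens(nRays);

  for (int q = 0; q < n; ++q) {
    double px = coords(q, 0), py = coords(q, 1), pz = coords(q, 2);
    double dx = dirs(q, 0), dy = dirs(q, 1), dz = dirs(q, 2);
    int ix = (int)std::lround(px) - 1, iy = (int)std::lround(py) - 1,
        iz = (int)std::lround(pz) - 1;
    bool onFg = ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 &&
                iz < nz && vol[(long)ix + (long)nx * ((long)iy + (long)ny * iz)];
    out(q, 3) = onFg ? 1 : 0;
    if (!onFg) { out(q, 0) = NA_REAL; continue; }

    // orthonormal basis {u, v} perpendicular to d: u = normalize(d x e),
    // e the coordinate axis least parallel to d; v = d x u
    double ax = std::fabs(dx), ay = std::fabs(dy), az = std::fabs(dz);
    double ex = 0, ey = 0, ez = 0;
    if (ax <= ay && ax <= az) ex = 1;
    else if (ay <= az) ey = 1;
    else ez = 1;
    double ux = dy * ez - dz * ey, uy = dz * ex - dx * ez, uz = dx * ey - dy * ex;
    double un = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= un; uy /= un; uz /= un;
    double vx = dy * uz - dz * uy, vy = dz * ux - dx * uz, vz = dx * uy - dy * ux;

    for (int k = 0; k < nRays; ++k) {
      double a = 2.0 * M_PI * k / nRays;
      double rx = std::cos(a) * ux + std::sin(a) * vx;
      double ry = std::cos(a) * uy + std::sin(a) * vy;
      double rz = std::cos(a) * uz + std::sin(a) * vz;
      double t = step;
      rvalid[k] = 0; rcens[k] = 0; rdist[k] = NA_REAL;
      while (true) {
        if (t > maxMarch) { rdist[k] = maxMarch; rvalid[k] = 1; rcens[k] = 1; break; }
        int sx = (int)std::lround(px + t * rx) - 1;
        int sy = (int)std::lround(py + t * ry) - 1;
        int sz = (int)std::lround(pz + t * rz) - 1;
        if (sx < 0 || sx >= nx || sy < 0 || sy >= ny || sz < 0 || sz >= nz) {
          rvalid[k] = 0; // left the volume while still in foreground
          break;
        }
        if (!vol[(long)sx + (long)nx * ((long)sy + (long)ny * sz)]) {
          rdist[k] = t - step / 2.0; // midpoint of the exit step
          rvalid[k] = 1;
          break;
        }
        t += step;
      }
    }

    double sum = 0;
    int npairs = 0, cens = 0;
    for (int k = 0; k < half; ++k) {
      if (rvalid[k] && rvalid[k + half]) {
        sum += rdist[k] + rdist[k + half];
        ++npairs;
        if (rcens[k] || rcens[k + half]) cens = 1;
      }
    }
    out(q, 0) = npairs > 0 ? sum / npairs : NA_REAL;
    out(q, 1) = npairs;
    out(q, 2) = cens;
  }
  return out;
}
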