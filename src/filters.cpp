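#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3D arrays are column-major with dim = c(nx, ny, nz); x is the fastest axis.

static inline int mirrorIndex(int i, int n) {
  // scipy-style "reflect" boundary: (d c b a | a b c d | d c b a)
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Correlation of a 3D array with a 1D kernel along one axis (0, 1 or 2),
// mirror boundary. Kernel must have odd length; its centre is (len-1)/2.
// [[Rcpp::export]]
NumericVector cpp_conv3d_axis(NumericVector vol, IntegerVector dim,
                              NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int klen = kernel.size();
  if (klen % 2 == 0) stop("kernel length must be odd");
  const int kc = (klen - 1) / 2;
  NumericVector out(vol.size());

  const int n[3] = {nx, ny, nz};
  const long stride[3] = {1, (long)nx, (long)nx * ny};
  const int na = n[axis];
  const long sa = stride[axis];
  // the two remaining axes
  int a1 = (axis == 0) ? 1 : 0;
  int a2 = (axis == 2) ? 1 : 2;
  const int n1 = n[a1], n2 = n[a2];
  const long s1 = stride[a1], s2 = stride[a2];

  std::vector<double> line(na);
  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      const long base = j1 * s1 + j2 * s2;
      for (int i = 0; i < na; ++i) line[i] = vol[base + i * sa];
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        for (int k = 0; k < klen; ++k)
          acc += kernel[k] * line[mirrorIndex(i + k - kc, na)];
        out[base + i * sa] = acc;
      }
    }
  }
  return out;
}

// Mean over a cubic window of side w centred on each voxel, with the window
// clipped at the volume borders (average over the in-volume part only).
// For even w the window spans offsets [-(w-1)/2, w/2].
// [[Rcpp::export]]
NumericVector cpp_box_filter3d(NumericVector vol, IntegerVector dim, int w) {
  if (w < 1) stop("window must be >= 1");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int hlo = (w - 1) / 2, hhi = w / 2;
  NumericVector cur = clone(vol);

  const int n[3] = {nx, ny, nz};
  const long stride[3] = {1, (long)nx, (long)nx * ny};

  for (int axis = 0; axis < 3; ++axis) {
    const int na = n[axis];
    const long sa = stride[axis];
    int a1 = (axis == 0) ? 1 : 0;
    int a2 = (axis == 2) ? 1 : 2;
    const int n1 = n[a1], n2 = n[a2];
    const long s1 = stride[a1], s2 = stride[a2];
    std::vector<double> ps(na + 1);
    NumericVector nxt(cur.size());
    for (int j2 = 0; j2 < n2; ++j2) {
      for (int j1 = 0; j1 < n1; ++j1) {
        const long base = j1 * s1 + j2 * s2;
        ps[0] = 0.0;
        for (int i = 0; i < na; ++i) ps[i + 1] = ps[i] + cur[base + i * sa];
        for (int i = 0; i < na; ++i) {
          int lo = std::max(i - hlo, 0), hi = std::min(i + hhi, na - 1);
          nxt[base + i * sa] = ps[hi + 1] - ps[lo];
        }
      }
    }
    cur = nxt;
  }

  // normalise by the clipped-window voxel count (separable product)
  std::vector<std::vector<double>> cnt(3);
  for (int axis = 0; axis < 3; ++axis) {
    cnt[axis].resize(n[axis]);
    for (int i = 0; i < n[axis]; ++i) {
      int lo = std::max(i - hlo, 0), hi = std::min(i + hhi, n[axis] - 1);
      cnt[axis][i] = hi - lo + 1;
    }
  }
  long idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const double cyz = cnt[1][y] * cnt[2][z];
      for (int x = 0; x < nx; ++x, ++idx) cur[idx] /= cnt[0][x] * cyz;
    }
  return cur;
}
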