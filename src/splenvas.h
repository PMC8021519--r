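#ifndef SPLENVAS_H
#define SPLENVAS_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

// Volumes are R arrays dim (H, W, Z): first index y (row), second x (col),
// third z (slice); value at (y,x,z) sits at y + H*(x + W*z).
// Images are H x W matrices with the same (y,x) convention.
// World coordinates: voxel (ix,iy,iz) 0-based has center
//   (ox + (ix+0.5)*sx, oy + (iy+0.5)*sy, oz + (iz+0.5)*sz).

inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// bilinear sample with border clamp; x along columns, y along rows
inline double bilinear(const double *img, int H, int W, double x, double y) {
  if (x < 0) x = 0; if (x > W - 1) x = W - 1;
  if (y < 0) y = 0; if (y > H - 1) y = H - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 > W - 2) x0 = W - 2 < 0 ? 0 : W - 2;
  if (y0 > H - 2) y0 = H - 2 < 0 ? 0 : H - 2;
  int x1 = x0 + 1 < W ? x0 + 1 : x0;
  int y1 = y0 + 1 < H ? y0 + 1 : y0;
  double fx = x - x0, fy = y - y0;
  double v00 = img[y0 + (size_t)H * x0], v10 = img[y0 + (size_t)H * x1];
  double v01 = img[y1 + (size_t)H * x0], v11 = img[y1 + (size_t)H * x1];
  return (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11);
}

// squared distance from point p to segment [a,b] in 3D
inline double pt_seg_d2(const double *p, const double *a, const double *b) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double denom = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];
  double t = denom > 0 ? (ap[0] * ab[0] + ap[1] * ab[1] + ap[2] * ab[2]) / denom : 0.0;
  t = clampd(t, 0.0, 1.0);
  double dx = ap[0] - t * ab[0], dy = ap[1] - t * ab[1], dz = ap[2] - t * ab[2];
  return dx * dx + dy * dy + dz * dz;
}

#endif
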