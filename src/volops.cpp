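#include "splenvas.h"
using namespace Rcpp;

// ---- separable Gaussian on an (H, W, Z) array ------------------------------
// sigma per axis in voxels (order: y, x, z); sigma <= 0 skips the axis.
// Boundary: reflect (edge value repeated, scipy-style 'reflect').

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(4.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  return k;
}

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// convolve along one axis of the (H,W,Z) volume, in place via buffer
static void conv_axis(std::vector<double> &v, int H, int W, int Z, int axis,
                      const std::vector<double> &k) {
  int r = ((int)k.size() - 1) / 2;
  int n = axis == 0 ? H : (axis == 1 ? W : Z);
  size_t stride = axis == 0 ? 1 : (axis == 1 ? (size_t)H : (size_t)H * W);
  std::vector<double> line(n);
  int no = axis == 0 ? W : H, ni = axis == 2 ? W : Z;  // the two other dims
  for (int a = 0; a < no; ++a) {
    for (int b = 0; b < ni; ++b) {
      size_t base;
      if (axis == 0) base = (size_t)H * a + (size_t)H * W * b;         // a=x, b=z
      else if (axis == 1) base = (size_t)a + (size_t)H * W * b;        // a=y, b=z
      else base = (size_t)a + (size_t)H * b;                           // a=y, b=x
      for (int i = 0; i < n; ++i) line[i] = v[base + stride * i];
      for (int i = 0; i < n; ++i) {
        double s = 0;
        for (int j = -r; j <= r; ++j) s += k[j + r] * line[reflect_idx(i + j, n)];
        v[base + stride * i] = s;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, NumericVector sigma) {
  IntegerVector dm = vol.attr("dim");
  int H = dm[0], W = dm[1], Z = dm.size() > 2 ? dm[2] : 1;
  std::vector<double> v(vol.begin(), vol.end());
  if (sigma[0] > 0) conv_axis(v, H, W, Z, 0, gauss_kernel(sigma[0]));
  if (sigma[1] > 0) conv_axis(v, H, W, Z, 1, gauss_kernel(sigma[1]));
  if (Z > 1 && sigma.size() > 2 && sigma[2] > 0) conv_axis(v, H, W, Z, 2, gauss_kernel(sigma[2]));
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dm;
  return out;
}

// ---- grayscale morphology with a digital-ellipsoid structuring element -----
// Ellipsoid radii (rx, ry, rz) in voxels; the SE is the set of integer offsets
// (dx,dy,dz) with sum((d/r)^2) <= 1 (terms with r==0 require d==0).
// Decomposition: union over (dx,dz) of y-segments of halfwidth wy(dx,dz);
// the dilation is a running 1-D max along the contiguous y axis (van
// Herk/Gil-Werman) per (dx,dz) shift, combined by max.  Outside the volume is
// -Inf for dilation and +Inf for erosion, so borders behave like "ignore".

static void vanherk_line(const double *in, double *out, int n, int w, bool mx) {
  // running max (mx) or min over window [i-w, i+w]
  if (w <= 0) { std::copy(in, in + n, out); return; }
  int k = 2 * w + 1;
  std::vector<double> fwd(n), bwd(n);
  for (int blk = 0; blk < n; blk += k) {
    int end = std::min(blk + k, n);
    fwd[blk] = in[blk];
    for (int i = blk + 1; i < end; ++i)
      fwd[i] = mx ? std::max(fwd[i - 1], in[i]) : std::min(fwd[i - 1], in[i]);
    bwd[end - 1] = in[end - 1];
    for (int i = end - 2; i >= blk; --i)
      bwd[i] = mx ? std::max(bwd[i + 1], in[i]) : std::min(bwd[i + 1], in[i]);
  }
  for (int i = 0; i < n; ++i) {
    int lo = i - w, hi = i + w;
    if (lo >= 0 && hi < n) {
      out[i] = mx ? std::max(bwd[lo], fwd[hi]) : std::min(bwd[lo], fwd[hi]);
    } else {  // window clipped at the border: exact scan (rare, O(w))
      if (lo < 0) lo = 0;
      if (hi >= n) hi = n - 1;
      double v = in[lo];
      for (int j = lo + 1; j <= hi; ++j) v = mx ? std::max(v, in[j]) : std::min(v, in[j]);
      out[i] = v;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_morph3d(NumericVector vol, double rx, double ry, double rz,
                          bool dilate) {
  IntegerVector dm = vol.attr("dim");
  int H = dm[0], W = dm[1], Z = dm.size() > 2 ? dm[2] : 1;
  size_t N = (size_t)H * W * Z;
  const double pad = dilate ? -HUGE_VAL : HUGE_VAL;
  std::vector<double> out(N, pad);
  int Rx = (int)std::floor(rx), Rz = (int)std::floor(rz);
  std::vector<double> lineout(H);

  for (int dz = -Rz; dz <= Rz; ++dz) {
    double tz = rz > 0 ? (double)dz / rz : 0.0;
    if (rz == 0 && dz != 0) continue;
    for (int dx = -Rx; dx <= Rx; ++dx) {
      double tx = rx > 0 ? (double)dx / rx : 0.0;
      if (rx == 0 && dx != 0) continue;
      double rem = 1.0 - tx * tx - tz * tz;
      if (rem < 0) continue;
      int wy = ry > 0 ? (int)std::floor(ry * std::sqrt(rem)) : 0;
      for (int z = 0; z < Z; ++z) {
        int zz = z + dz;
        if (zz < 0 || zz >= Z) continue;
        for (int x = 0; x < W; ++x) {
          int xx = x + dx;
          if (xx < 0 || xx >= W) continue;
          const double *src = &vol[(size_t)H * xx + (size_t)H * W * zz];
          double *dst = &out[(size_t)H * x + (size_t)H * W * z];
          vanherk_line(src, lineout.data(), H, wy, dilate);
          if (dilate) {
            for (int y = 0; y < H; ++y) if (lineout[y] > dst[y]) dst[y] = lineout[y];
          } else {
            for (int y = 0; y < H; ++y) if (lineout[y] < dst[y]) dst[y] = lineout[y];
          }
        }
      }
    }
  }
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = dm;
  return res;
}

// Brute-force reference for tests: same SE definition, direct neighborhood max/min.
// [[Rcpp::export]]
NumericVector cpp_morph3d_brute(NumericVector vol, double rx, double ry, double rz,
                                bool dilate) {
  IntegerVector dm = vol.attr("dim");
  int H = dm[0], W = dm[1], Z = dm.size() > 2 ? dm[2] : 1;
  NumericVector out(vol.size());
  out.attr("dim") = dm;
  int Rx = (int)std::floor(rx), Ry = (int)std::floor(ry), Rz = (int)std::floor(rz);
  for (int z = 0; z < Z; ++z)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        double best = dilate ? -HUGE_VAL : HUGE_VAL;
        for (int dz = -Rz; dz <= Rz; ++dz)
          for (int dx = -Rx; dx <= Rx; ++dx)
            for (int dy = -Ry; dy <= Ry; ++dy) {
              double s = 0;
              if (rx > 0) s += (double)dx * dx / (rx * rx); else if (dx) continue;
              if (ry > 0) s += (double)dy * dy / (ry * ry); else if (dy) continue;
              if (rz > 0) s += (double)dz * dz / (rz * rz); else if (dz) continue;
              if (s > 1.0) continue;
              int yy = y + dy, xx = x + dx, zz = z + dz;
              if (yy < 0 || yy >= H || xx < 0 || xx >= W || zz < 0 || zz >= Z) continue;
              double v = vol[yy + (size_t)H * (xx + (size_t)W * zz)];
              best = dilate ? std::max(best, v) : std::min(best, v);
            }
        out[y + (size_t)H * (x + (size_t)W * z)] = best;
      }
  return out;
}
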