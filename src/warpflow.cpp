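#include "splenvas.h"
using namespace Rcpp;

// rigid warp about the image center: forward map p' = R(p - c) + c + t.
// The output is sampled backward: out(q) = in(R^T (q - c - t) + c).
// fill is used outside the input footprint.
// [[Rcpp::export]]
NumericMatrix cpp_warp_rigid(NumericMatrix img, double theta, double tx,
                             double ty, double fill) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  double ct = std::cos(theta), st = std::sin(theta);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double qx = x - cx - tx, qy = y - cy - ty;
      double sx = ct * qx + st * qy + cx;   // R^T
      double sy = -st * qx + ct * qy + cy;
      if (sx < -0.5 || sx > W - 0.5 || sy < -0.5 || sy > H - 0.5)
        out(y, x) = fill;
      else
        out(y, x) = bilinear(&img[0], H, W, sx, sy);
    }
  }
  return out;
}

// backward warp along a dense flow field: out(p) = in(p + s*flow(p))
// [[Rcpp::export]]
NumericMatrix cpp_warp_flow(NumericMatrix img, NumericMatrix u, NumericMatrix v,
                            double s) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      out(y, x) = bilinear(&img[0], H, W, x + s * u(y, x), y + s * v(y, x));
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix img, int H2, int W2) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H2, W2);
  double fy = H2 > 1 ? (double)(H - 1) / (H2 - 1) : 0.0;
  double fx = W2 > 1 ? (double)(W - 1) / (W2 - 1) : 0.0;
  for (int x = 0; x < W2; ++x)
    for (int y = 0; y < H2; ++y)
      out(y, x) = bilinear(&img[0], H, W, x * fx, y * fy);
  return out;
}

NumericVector cpp_gauss3d(NumericVector vol, NumericVector sigma);  // volops.cpp

static NumericMatrix blur2(NumericMatrix img, double sigma) {
  NumericVector v = clone(img);
  v.attr("dim") = IntegerVector::create(img.nrow(), img.ncol(), 1);
  NumericVector out = cpp_gauss3d(v, NumericVector::create(sigma, sigma, 0));
  NumericMatrix res(img.nrow(), img.ncol());
  std::copy(out.begin(), out.end(), res.begin());
  return res;
}

static NumericMatrix downsample2(NumericMatrix img) {
  NumericMatrix b = blur2(img, 1.0);
  int H2 = (img.nrow() + 1) / 2, W2 = (img.ncol() + 1) / 2;
  NumericMatrix out(H2, W2);
  for (int x = 0; x < W2; ++x)
    for (int y = 0; y < H2; ++y)
      out(y, x) = b(std::min(2 * y, img.nrow() - 1), std::min(2 * x, img.ncol() - 1));
  return out;
}

// Dense optical flow A -> B (coarse-to-fine iterative Lucas-Kanade with a
// Gaussian integration window).  Returns an (H, W, 2) array: u (x-shift) and
// v (y-shift) such that B(p) ~ A(p + flow(p))... by convention here,
// warp(B, flow, 1) aligns B onto A, i.e. A(p) ~ B(p + flow(p)).
// [[Rcpp::export]]
NumericVector cpp_flow_lk(NumericMatrix A, NumericMatrix B, int levels,
                          int iters, double win_sigma) {
  std::vector<NumericMatrix> pa, pb;
  pa.push_back(A); pb.push_back(B);
  for (int l = 1; l < levels; ++l) {
    if (pa.back().nrow() < 16 || pa.back().ncol() < 16) break;
    pa.push_back(downsample2(pa.back()));
    pb.push_back(downsample2(pb.back()));
  }
  int nl = pa.size();
  int Hc = pa[nl - 1].nrow(), Wc = pa[nl - 1].ncol();
  NumericMatrix u(Hc, Wc), v(Hc, Wc);

  for (int l = nl - 1; l >= 0; --l) {
    NumericMatrix a = pa[l], b = pb[l];
    int H = a.nrow(), W = a.ncol();
    if ((int)u.nrow() != H || (int)u.ncol() != W) {
      NumericMatrix u2 = cpp_resize_bilinear(u, H, W);
      NumericMatrix v2 = cpp_resize_bilinear(v, H, W);
      for (int i = 0; i < H * W; ++i) { u2[i] *= 2.0; v2[i] *= 2.0; }
      u = u2; v = v2;
    }
    for (int it = 0; it < iters; ++it) {
      NumericMatrix bw = cpp_warp_flow(b, u, v, 1.0);
      NumericMatrix Ix(H, W), Iy(H, W), It(H, W);
      for (int x = 0; x < W; ++x)
        for (int y = 0; y < H; ++y) {
          int xm = std::max(x - 1, 0), xp = std::min(x + 1, W - 1);
          int ym = std::max(y - 1, 0), yp = std::min(y + 1, H - 1);
          Ix(y, x) = 0.25 * (a(y, xp) - a(y, xm) + bw(y, xp) - bw(y, xm));
          Iy(y, x) = 0.25 * (a(yp, x) - a(ym, x) + bw(yp, x) - bw(ym, x));
          It(y, x) = bw(y, x) - a(y, x);
        }
      NumericMatrix xx(H, W), xy(H, W), yy(H, W), xt(H, W), yt(H, W);
      for (int i = 0; i < H * W; ++i) {
        xx[i] = Ix[i] * Ix[i]; xy[i] = Ix[i] * Iy[i]; yy[i] = Iy[i] * Iy[i];
        xt[i] = Ix[i] * It[i]; yt[i] = Iy[i] * It[i];
      }
      xx = blur2(xx, win_sigma); xy = blur2(xy, win_sigma);
      yy = blur2(yy, win_sigma); xt = blur2(xt, win_sigma);
      yt = blur2(yt, win_sigma);
      double tr = 0;
      for (int i = 0; i < H * W; ++i) tr += xx[i] + yy[i];
      double eps = 1e-4 * tr / (H * W) + 1e-9;
      for (int i = 0; i < H * W; ++i) {
        double det = (xx[i] + eps) * (yy[i] + eps) - xy[i] * xy[i];
        double du = (-(xt[i]) * (yy[i] + eps) + xy[i] * yt[i]) / det;
        double dv = (-(yt[i]) * (xx[i] + eps) + xy[i] * xt[i]) / det;
        du = clampd(du, -4, 4); dv = clampd(dv, -4, 4);
        u[i] += du; v[i] += dv;
      }
      u = blur2(u, 1.0); v = blur2(v, 1.0);
    }
  }
  NumericVector out((size_t)A.nrow() * A.ncol() * 2);
  std::copy(u.begin(), u.end(), out.begin());
  std::copy(v.begin(), v.end(), out.begin() + (size_t)A.nrow() * A.ncol());
  out.attr("dim") = IntegerVector::create(A.nrow(), A.ncol(), 2);
  return out;
}

// local maxima of an image above a threshold within a square radius
// returns n x 3 matrix (x, y, value), 0-based pixel coordinates
// [[Rcpp::export]]
NumericMatrix cpp_local_maxima(NumericMatrix img, int radius, double thresh) {
  int H = img.nrow(), W = img.ncol();
  std::vector<double> pts;
  for (int x = radius; x < W - radius; ++x)
    for (int y = radius; y < H - radius; ++y) {
      double v = img(y, x);
      if (v < thresh) continue;
      bool ismax = true;
      for (int dx = -radius; dx <= radius && ismax; ++dx)
        for (int dy = -radius; dy <= radius; ++dy) {
          if (dx == 0 && dy == 0) continue;
          double w = img(y + dy, x + dx);
          if (w > v || (w == v && (dy < 0 || (dy == 0 && dx < 0)))) { ismax = false; break; }
        }
      if (ismax) { pts.push_back(x); pts.push_back(y); pts.push_back(v); }
    }
  int n = pts.size() / 3;
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = pts[3 * i]; out(i, 1) = pts[3 * i + 1]; out(i, 2) = pts[3 * i + 2];
  }
  return out;
}
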