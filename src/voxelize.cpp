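#include "splenvas.h"
using namespace Rcpp;

// Rasterize capsules (segment + radius, spheres as zero-length segments) into
// an existing (H,W,Z) occupancy volume by voxelwise max.
// segs: n x 7 (x1,y1,z1,x2,y2,z2,r) in um, world coords.
// Voxel centers: world = origin + (index + 0.5) * spacing (0-based indices).
// soft=TRUE gives partial-volume occupancy ramped over one mean voxel size;
// soft=FALSE gives strict binary inside (d <= r).
// [[Rcpp::export]]
NumericVector cpp_rasterize_capsules(NumericVector vol, NumericMatrix segs,
                                     NumericVector spacing, NumericVector origin,
                                     bool soft) {
  IntegerVector dm = vol.attr("dim");
  int H = dm[0], W = dm[1], Z = dm[2];
  NumericVector out = clone(vol);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];
  double h = (sx + sy + sz) / 3.0;
  for (int s = 0; s < segs.nrow(); ++s) {
    double a[3] = {segs(s, 0), segs(s, 1), segs(s, 2)};
    double b[3] = {segs(s, 3), segs(s, 4), segs(s, 5)};
    double r = segs(s, 6);
    double m = r + (soft ? h : 0.0) + 1e-9;
    int x0 = std::max(0, (int)std::floor((std::min(a[0], b[0]) - m - ox) / sx - 0.5));
    int x1 = std::min(W - 1, (int)std::ceil((std::max(a[0], b[0]) + m - ox) / sx - 0.5));
    int y0 = std::max(0, (int)std::floor((std::min(a[1], b[1]) - m - oy) / sy - 0.5));
    int y1 = std::min(H - 1, (int)std::ceil((std::max(a[1], b[1]) + m - oy) / sy - 0.5));
    int z0 = std::max(0, (int)std::floor((std::min(a[2], b[2]) - m - oz) / sz - 0.5));
    int z1 = std::min(Z - 1, (int)std::ceil((std::max(a[2], b[2]) + m - oz) / sz - 0.5));
    for (int iz = z0; iz <= z1; ++iz) {
      double pz = oz + (iz + 0.5) * sz;
      for (int ix = x0; ix <= x1; ++ix) {
        double px = ox + (ix + 0.5) * sx;
        for (int iy = y0; iy <= y1; ++iy) {
          double p[3] = {px, oy + (iy + 0.5) * sy, pz};
          double d = std::sqrt(pt_seg_d2(p, a, b));
          double occ = soft ? clampd(0.5 + (r - d) / h, 0.0, 1.0)
                            : (d <= r ? 1.0 : 0.0);
          size_t idx = (size_t)iy + (size_t)H * (ix + (size_t)W * iz);
          if (occ > out[idx]) out[idx] = occ;
        }
      }
    }
  }
  return out;
}

// Rasterize one tubular shell (a capillary sheath): voxels whose minimal
// distance to the covered polyline (given as segments) lies in [rin, rout].
// [[Rcpp::export]]
NumericVector cpp_rasterize_shell(NumericVector vol, NumericMatrix segs,
                                  double rin, double rout,
                                  NumericVector spacing, NumericVector origin,
                                  bool soft) {
  IntegerVector dm = vol.attr("dim");
  int H = dm[0], W = dm[1], Z = dm[2];
  NumericVector out = clone(vol);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];
  double h = (sx + sy + sz) / 3.0;
  double lox = HUGE_VAL, hix = -HUGE_VAL, loy = HUGE_VAL, hiy = -HUGE_VAL,
         loz = HUGE_VAL, hiz = -HUGE_VAL;
  for (int s = 0; s < segs.nrow(); ++s) {
    lox = std::min({lox, segs(s, 0), segs(s, 3)});
    hix = std::max({hix, segs(s, 0), segs(s, 3)});
    loy = std::min({loy, segs(s, 1), segs(s, 4)});
    hiy = std::max({hiy, segs(s, 1), segs(s, 4)});
    loz = std::min({loz, segs(s, 2), segs(s, 5)});
    hiz = std::max({hiz, segs(s, 2), segs(s, 5)});
  }
  double m = rout + (soft ? h : 0.0) + 1e-9;
  int x0 = std::max(0, (int)std::floor((lox - m - ox) / sx - 0.5));
  int x1 = std::min(W - 1, (int)std::ceil((hix + m - ox) / sx - 0.5));
  int y0 = std::max(0, (int)std::floor((loy - m - oy) / sy - 0.5));
  int y1 = std::min(H - 1, (int)std::ceil((hiy + m - oy) / sy - 0.5));
  int z0 = std::max(0, (int)std::floor((loz - m - oz) / sz - 0.5));
  int z1 = std::min(Z - 1, (int)std::ceil((hiz + m - oz) / sz - 0.5));
  for (int iz = z0; iz <= z1; ++iz)
    for (int ix = x0; ix <= x1; ++ix)
      for (int iy = y0; iy <= y1; ++iy) {
        double p[3] = {ox + (ix + 0.5) * sx, oy + (iy + 0.5) * sy, oz + (iz + 0.5) * sz};
        double d2 = HUGE_VAL;
        for (int s = 0; s < segs.nrow(); ++s) {
          double a[3] = {segs(s, 0), segs(s, 1), segs(s, 2)};
          double b[3] = {segs(s, 3), segs(s, 4), segs(s, 5)};
          d2 = std::min(d2, pt_seg_d2(p, a, b));
        }
        double d = std::sqrt(d2);
        double occ;
        if (soft)
          occ = clampd(0.5 + (rout - d) / h, 0.0, 1.0) *
                clampd(0.5 + (d - rin) / h, 0.0, 1.0);
        else
          occ = (d >= rin && d <= rout) ? 1.0 : 0.0;
        size_t idx = (size_t)iy + (size_t)H * (ix + (size_t)W * iz);
        if (occ > out[idx]) out[idx] = occ;
      }
  return out;
}
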