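#include "splenvas.h"
#include <queue>
using namespace Rcpp;

// separating-axis triangle/axis-aligned-box overlap (Akenine-Moller);
// box given by center and half size h (cube)
static bool tri_box_overlap(const double c[3], double h, double v0[3],
                            double v1[3], double v2[3]) {
  double a[3], b[3], d[3];
  for (int j = 0; j < 3; ++j) {
    a[j] = v0[j] - c[j]; b[j] = v1[j] - c[j]; d[j] = v2[j] - c[j];
  }
  // box axes
  for (int j = 0; j < 3; ++j) {
    double mn = std::min({a[j], b[j], d[j]}), mx = std::max({a[j], b[j], d[j]});
    if (mn > h || mx < -h) return false;
  }
  double e0[3], e1[3], e2[3], nrm[3];
  for (int j = 0; j < 3; ++j) {
    e0[j] = b[j] - a[j]; e1[j] = d[j] - b[j]; e2[j] = a[j] - d[j];
  }
  nrm[0] = e0[1] * e1[2] - e0[2] * e1[1];
  nrm[1] = e0[2] * e1[0] - e0[0] * e1[2];
  nrm[2] = e0[0] * e1[1] - e0[1] * e1[0];
  // plane of the triangle
  double dist = nrm[0] * a[0] + nrm[1] * a[1] + nrm[2] * a[2];
  double rad = h * (std::fabs(nrm[0]) + std::fabs(nrm[1]) + std::fabs(nrm[2]));
  if (std::fabs(dist) > rad) return false;
  // 9 cross-product axes
  const double *E[3] = {e0, e1, e2};
  const double *V[3] = {a, b, d};
  for (int ei = 0; ei < 3; ++ei) {
    for (int j = 0; j < 3; ++j) {
      int j1 = (j + 1) % 3, j2 = (j + 2) % 3;
      // axis = unit_j x E[ei] -> components only in j1, j2
      double ax1 = -E[ei][j2], ax2 = E[ei][j1];
      double p0 = ax1 * V[0][j1] + ax2 * V[0][j2];
      double p1 = ax1 * V[1][j1] + ax2 * V[1][j2];
      double p2 = ax1 * V[2][j1] + ax2 * V[2][j2];
      double mn = std::min({p0, p1, p2}), mx = std::max({p0, p1, p2});
      double r = h * (std::fabs(ax1) + std::fabs(ax2));
      if (mn > r || mx < -r) return false;
    }
  }
  return true;
}

// Rasterize a triangle soup into an n^3 cell grid (origin/cell in world um)
// conservatively: a cell is marked iff the triangle overlaps it (separating
// axis test), so the rasterized surface has no pinholes a 6-connected flood
// fill could leak through.  Used by the octree-style watertight repair and
// by the inside-mesh coverage test.
// [[Rcpp::export]]
RawVector cpp_voxelize_mesh(NumericMatrix verts, IntegerMatrix faces, int n,
                            NumericVector origin, double cell) {
  RawVector grid((size_t)n * n * n);  // zero-initialised
  double ox = origin[0], oy = origin[1], oz = origin[2];
  double h = cell / 2;
  for (int f = 0; f < faces.nrow(); ++f) {
    double a[3], b[3], c[3];
    for (int j = 0; j < 3; ++j) {
      a[j] = verts(faces(f, 0) - 1, j);
      b[j] = verts(faces(f, 1) - 1, j);
      c[j] = verts(faces(f, 2) - 1, j);
    }
    int lo[3], hi[3];
    bool skip = false;
    for (int j = 0; j < 3; ++j) {
      double o = j == 0 ? ox : (j == 1 ? oy : oz);
      double mn = std::min({a[j], b[j], c[j]}), mx = std::max({a[j], b[j], c[j]});
      lo[j] = std::max(0, (int)std::floor((mn - o) / cell));
      hi[j] = std::min(n - 1, (int)std::floor((mx - o) / cell));
      if (lo[j] > hi[j]) skip = true;
    }
    if (skip) continue;
    for (int iz = lo[2]; iz <= hi[2]; ++iz)
      for (int ix = lo[0]; ix <= hi[0]; ++ix)
        for (int iy = lo[1]; iy <= hi[1]; ++iy) {
          double cc[3] = {ox + (ix + 0.5) * cell, oy + (iy + 0.5) * cell,
                          oz + (iz + 0.5) * cell};
          if (tri_box_overlap(cc, h * 1.0000001, a, b, c))
            grid[(size_t)iy + (size_t)n * (ix + (size_t)n * iz)] = 1;
        }
  }
  return grid;
}

// 6-connected flood fill from the grid boundary across empty cells; returns a
// 0/1 occupancy where 1 = surface cell or enclosed interior.
// [[Rcpp::export]]
RawVector cpp_fill_occupancy(RawVector grid, int n) {
  size_t N = (size_t)n * n * n;
  std::vector<uint8_t> state(grid.begin(), grid.end());  // 0 empty, 1 surface
  std::queue<size_t> q;
  auto idx = [n](int y, int x, int z) {
    return (size_t)y + (size_t)n * (x + (size_t)n * z);
  };
  for (int z = 0; z < n; ++z)
    for (int x = 0; x < n; ++x)
      for (int y = 0; y < n; ++y) {
        if (z > 0 && z < n - 1 && x > 0 && x < n - 1 && y > 0 && y < n - 1) continue;
        size_t i = idx(y, x, z);
        if (state[i] == 0) { state[i] = 2; q.push(i); }
      }
  const int d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    size_t i = q.front(); q.pop();
    int y = i % n, x = (i / n) % n, z = i / ((size_t)n * n);
    for (auto &dd : d) {
      int yy = y + dd[0], xx = x + dd[1], zz = z + dd[2];
      if (yy < 0 || xx < 0 || zz < 0 || yy >= n || xx >= n || zz >= n) continue;
      size_t j = idx(yy, xx, zz);
      if (state[j] == 0) { state[j] = 2; q.push(j); }
    }
  }
  RawVector out(N);
  for (size_t i = 0; i < N; ++i) out[i] = state[i] == 2 ? 0 : 1;
  return out;
}
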