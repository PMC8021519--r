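#include "splenvas.h"
#include <unordered_map>
#include <functional>
using namespace Rcpp;

// exact point-triangle distance: plane projection if the foot lies inside,
// else the nearest of the three edge segments
static double pt_tri_d2(const double *p, const double *a, const double *b,
                        const double *c) {
  double ab[3], ac[3], ap[3];
  for (int j = 0; j < 3; ++j) {
    ab[j] = b[j] - a[j]; ac[j] = c[j] - a[j]; ap[j] = p[j] - a[j];
  }
  double n[3] = {ab[1] * ac[2] - ab[2] * ac[1], ab[2] * ac[0] - ab[0] * ac[2],
                 ab[0] * ac[1] - ab[1] * ac[0]};
  double nn = n[0] * n[0] + n[1] * n[1] + n[2] * n[2];
  if (nn > 0) {
    double dist = (ap[0] * n[0] + ap[1] * n[1] + ap[2] * n[2]);
    double q[3];  // foot of perpendicular
    for (int j = 0; j < 3; ++j) q[j] = p[j] - dist * n[j] / nn - a[j];
    // barycentric test of q (relative to a)
    double d00 = ab[0]*ab[0]+ab[1]*ab[1]+ab[2]*ab[2];
    double d01 = ab[0]*ac[0]+ab[1]*ac[1]+ab[2]*ac[2];
    double d11 = ac[0]*ac[0]+ac[1]*ac[1]+ac[2]*ac[2];
    double dq0 = q[0]*ab[0]+q[1]*ab[1]+q[2]*ab[2];
    double dq1 = q[0]*ac[0]+q[1]*ac[1]+q[2]*ac[2];
    double den = d00 * d11 - d01 * d01;
    if (den > 0) {
      double u = (d11 * dq0 - d01 * dq1) / den;
      double v = (d00 * dq1 - d01 * dq0) / den;
      if (u >= 0 && v >= 0 && u + v <= 1) return dist * dist / nn;
    }
  }
  double d2 = pt_seg_d2(p, a, b);
  d2 = std::min(d2, pt_seg_d2(p, a, c));
  d2 = std::min(d2, pt_seg_d2(p, b, c));
  return d2;
}

// [[Rcpp::export]]
NumericVector cpp_tri_dist_brute(NumericMatrix pts, NumericMatrix verts,
                                 IntegerMatrix faces) {
  NumericVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double best = HUGE_VAL;
    for (int f = 0; f < faces.nrow(); ++f) {
      double a[3], b[3], c[3];
      for (int j = 0; j < 3; ++j) {
        a[j] = verts(faces(f, 0) - 1, j);
        b[j] = verts(faces(f, 1) - 1, j);
        c[j] = verts(faces(f, 2) - 1, j);
      }
      best = std::min(best, pt_tri_d2(p, a, b, c));
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// grid-accelerated exact min distance from each point to a triangle mesh
// [[Rcpp::export]]
NumericVector cpp_mesh_distance(NumericMatrix pts, NumericMatrix verts,
                                IntegerMatrix faces, double cell) {
  int nf = faces.nrow();
  double lo[3] = {HUGE_VAL, HUGE_VAL, HUGE_VAL}, hi[3] = {-HUGE_VAL, -HUGE_VAL, -HUGE_VAL};
  for (int i = 0; i < verts.nrow(); ++i)
    for (int j = 0; j < 3; ++j) {
      lo[j] = std::min(lo[j], verts(i, j));
      hi[j] = std::max(hi[j], verts(i, j));
    }
  int ng[3];
  for (int j = 0; j < 3; ++j)
    ng[j] = std::max(1, (int)std::ceil((hi[j] - lo[j]) / cell) + 1);
  auto cidx = [&](int ix, int iy, int iz) {
    return (size_t)ix + (size_t)ng[0] * (iy + (size_t)ng[1] * iz);
  };
  std::vector<std::vector<int>> bins((size_t)ng[0] * ng[1] * ng[2]);
  for (int f = 0; f < nf; ++f) {
    double flo[3] = {HUGE_VAL, HUGE_VAL, HUGE_VAL}, fhi[3] = {-HUGE_VAL, -HUGE_VAL, -HUGE_VAL};
    for (int k = 0; k < 3; ++k)
      for (int j = 0; j < 3; ++j) {
        double v = verts(faces(f, k) - 1, j);
        flo[j] = std::min(flo[j], v); fhi[j] = std::max(fhi[j], v);
      }
    int c0[3], c1[3];
    for (int j = 0; j < 3; ++j) {
      c0[j] = clampd(std::floor((flo[j] - lo[j]) / cell), 0, ng[j] - 1);
      c1[j] = clampd(std::floor((fhi[j] - lo[j]) / cell), 0, ng[j] - 1);
    }
    for (int iz = c0[2]; iz <= c1[2]; ++iz)
      for (int iy = c0[1]; iy <= c1[1]; ++iy)
        for (int ix = c0[0]; ix <= c1[0]; ++ix)
          bins[cidx(ix, iy, iz)].push_back(f);
  }

  NumericVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    int pc[3];
    for (int j = 0; j < 3; ++j)
      pc[j] = (int)clampd(std::floor((p[j] - lo[j]) / cell), 0, ng[j] - 1);
    double best = HUGE_VAL;
    // distance from p to its (clamped) home cell box, for the safe stop rule
    double off2 = 0;
    for (int j = 0; j < 3; ++j) {
      double blo = lo[j] + pc[j] * cell, bhi = blo + cell;
      double d = p[j] < blo ? blo - p[j] : (p[j] > bhi ? p[j] - bhi : 0);
      off2 += d * d;
    }
    double off = std::sqrt(off2);
    int maxring = ng[0] + ng[1] + ng[2];
    for (int r = 0; r <= maxring; ++r) {
      // any cell at Chebyshev ring r is at least (r-1)*cell - off away from p
      if (best < HUGE_VAL && r > 1) {
        double safe = (r - 1) * cell - off;
        if (safe > 0 && safe * safe > best) break;
      }
      int x0 = pc[0] - r, x1 = pc[0] + r;
      int y0 = pc[1] - r, y1 = pc[1] + r;
      int z0 = pc[2] - r, z1 = pc[2] + r;
      for (int iz = std::max(z0, 0); iz <= std::min(z1, ng[2] - 1); ++iz)
        for (int iy = std::max(y0, 0); iy <= std::min(y1, ng[1] - 1); ++iy)
          for (int ix = std::max(x0, 0); ix <= std::min(x1, ng[0] - 1); ++ix) {
            int ch = std::max({std::abs(ix - pc[0]), std::abs(iy - pc[1]),
                               std::abs(iz - pc[2])});
            if (ch != r) continue;  // ring shell only
            // exact distance from p to this cell's box
            double bd2 = 0;
            double blo, bhi, d;
            blo = lo[0] + ix * cell; bhi = blo + cell;
            d = p[0] < blo ? blo - p[0] : (p[0] > bhi ? p[0] - bhi : 0); bd2 += d * d;
            blo = lo[1] + iy * cell; bhi = blo + cell;
            d = p[1] < blo ? blo - p[1] : (p[1] > bhi ? p[1] - bhi : 0); bd2 += d * d;
            blo = lo[2] + iz * cell; bhi = blo + cell;
            d = p[2] < blo ? blo - p[2] : (p[2] > bhi ? p[2] - bhi : 0); bd2 += d * d;
            if (bd2 >= best) continue;
            for (int f : bins[cidx(ix, iy, iz)]) {
              double a[3], b[3], c[3];
              for (int j = 0; j < 3; ++j) {
                a[j] = verts(faces(f, 0) - 1, j);
                b[j] = verts(faces(f, 1) - 1, j);
                c[j] = verts(faces(f, 2) - 1, j);
              }
              best = std::min(best, pt_tri_d2(p, a, b, c));
            }
          }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Taubin lambda/mu smoothing with uniform (umbrella) weights
// [[Rcpp::export]]
NumericMatrix cpp_taubin(NumericMatrix verts, IntegerMatrix faces, double lambda,
                         double mu, int iters) {
  int nv = verts.nrow();
  std::vector<std::vector<int>> nb(nv);
  for (int f = 0; f < faces.nrow(); ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    nb[a].push_back(b); nb[a].push_back(c);
    nb[b].push_back(a); nb[b].push_back(c);
    nb[c].push_back(a); nb[c].push_back(b);
  }
  for (auto &v : nb) {
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
  }
  NumericMatrix cur = clone(verts);
  NumericMatrix nxt(nv, 3);
  for (int it = 0; it < 2 * iters; ++it) {
    double s = (it % 2 == 0) ? lambda : mu;
    for (int i = 0; i < nv; ++i) {
      if (nb[i].empty()) {
        for (int j = 0; j < 3; ++j) nxt(i, j) = cur(i, j);
        continue;
      }
      double m[3] = {0, 0, 0};
      for (int k : nb[i])
        for (int j = 0; j < 3; ++j) m[j] += cur(k, j);
      for (int j = 0; j < 3; ++j)
        nxt(i, j) = cur(i, j) + s * (m[j] / nb[i].size() - cur(i, j));
    }
    std::swap(cur, nxt);
  }
  return cur;
}

// connected components over mesh vertices (union-find); 1-based labels
// [[Rcpp::export]]
IntegerVector cpp_mesh_components(int nv, IntegerMatrix faces) {
  std::vector<int> parent(nv);
  for (int i = 0; i < nv; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int f = 0; f < faces.nrow(); ++f) {
    int a = find(faces(f, 0) - 1), b = find(faces(f, 1) - 1), c = find(faces(f, 2) - 1);
    parent[b] = a; parent[c] = find(a);
  }
  std::unordered_map<int, int> relabel;
  IntegerVector out(nv);
  for (int i = 0; i < nv; ++i) {
    int r = find(i);
    auto it = relabel.find(r);
    if (it == relabel.end()) { relabel[r] = relabel.size() + 1; }
    out[i] = relabel[r];
  }
  return out;
}

// per-edge face counts: returns counts of edges used once, twice, >twice
// [[Rcpp::export]]
IntegerVector cpp_edge_face_count(IntegerMatrix faces) {
  std::unordered_map<uint64_t, int> cnt;
  for (int f = 0; f < faces.nrow(); ++f)
    for (int e = 0; e < 3; ++e) {
      uint32_t a = faces(f, e), b = faces(f, (e + 1) % 3);
      uint64_t key = a < b ? ((uint64_t)a << 32) | b : ((uint64_t)b << 32) | a;
      cnt[key]++;
    }
  int c1 = 0, c2 = 0, cmore = 0;
  for (auto &kv : cnt) {
    if (kv.second == 1) c1++;
    else if (kv.second == 2) c2++;
    else cmore++;
  }
  return IntegerVector::create(c1, c2, cmore);
}
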