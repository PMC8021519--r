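#include "splenvas.h"
#include <unordered_map>
#include <array>
using namespace Rcpp;

// Crack-free marching cubes with a generated case table.
//
// A grid point is inside iff value >= iso (ties inside).  For each of the 256
// corner configurations the surface patch is derived at load time: on every
// cube face the iso-crossings are joined by marching-squares segments, with
// the ambiguous (diagonal) face case resolved by a fixed rule - the two
// inside corners are kept separate.  Because the rule depends only on the
// face's own corner states, the two cubes sharing a face derive the same
// segments, so every boundary segment is used by exactly two cubes and the
// triangulated surface is closed wherever the inside set does not touch the
// grid boundary.  Segments are walked into closed polygons and fan-
// triangulated; vertices sit on cube edges at the linear interpolation of
// the iso-crossing and are shared through an edge map.
//
// Corner numbering: bit0 = x, bit1 = y, bit2 = z.

static const int FACES[6][4] = {
  {0, 2, 6, 4},  // x = 0
  {1, 3, 7, 5},  // x = 1
  {0, 1, 5, 4},  // y = 0
  {2, 3, 7, 6},  // y = 1
  {0, 1, 3, 2},  // z = 0
  {4, 5, 7, 6}   // z = 1
};

struct CaseTable {
  // per case: list of polygons, each a list of cube-edge ids (edge = corner
  // pair packed as a*8+b, a<b)
  std::vector<std::vector<int>> poly[256];
  CaseTable() {
    for (int cs = 0; cs < 256; ++cs) {
      bool in[8];
      for (int c = 0; c < 8; ++c) in[c] = (cs >> c) & 1;
      // segments between crossed cube edges
      std::vector<std::pair<int, int>> segs;
      for (auto &f : FACES) {
        int cross[4], nc = 0;
        for (int i = 0; i < 4; ++i) {
          int a = f[i], b = f[(i + 1) % 4];
          if (in[a] != in[b]) cross[nc++] = i;
        }
        auto eid = [&](int i) {
          int a = f[i], b = f[(i + 1) % 4];
          return a < b ? a * 8 + b : b * 8 + a;
        };
        if (nc == 2) {
          segs.emplace_back(eid(cross[0]), eid(cross[1]));
        } else if (nc == 4) {
          // ambiguous: both diagonals differ; separate the inside corners
          for (int i = 0; i < 4; ++i) {
            if (!in[f[i]]) continue;
            // corner i is inside: join the crossings on its two face edges
            segs.emplace_back(eid((i + 3) % 4), eid(i));
          }
        }
      }
      if (segs.empty()) continue;
      // walk cycles: each crossed edge appears in exactly two segments
      std::unordered_map<int, std::vector<int>> adj;
      for (size_t s = 0; s < segs.size(); ++s) {
        adj[segs[s].first].push_back(s);
        adj[segs[s].second].push_back(s);
      }
      std::vector<bool> used(segs.size(), false);
      for (size_t s0 = 0; s0 < segs.size(); ++s0) {
        if (used[s0]) continue;
        std::vector<int> cyc;
        int cur = segs[s0].first;
        int s = s0;
        while (true) {
          used[s] = true;
          cyc.push_back(cur);
          int nxt = segs[s].first == cur ? segs[s].second : segs[s].first;
          int s2 = -1;
          for (int cand : adj[nxt])
            if (!used[cand]) s2 = cand;
          cur = nxt;
          if (s2 < 0) break;
          s = s2;
        }
        if (cyc.size() >= 3) poly[cs].push_back(cyc);
      }
    }
  }
};

static CaseTable CT;

struct MTAcc {
  std::vector<double> verts;
  std::vector<int> faces;
  std::unordered_map<uint64_t, int> edgemap;
};

template <typename GET>
static void march(GET getv, int H, int W, int Z, double iso,
                  double sx, double sy, double sz,
                  double ox, double oy, double oz, MTAcc &acc) {
  auto px = [&](size_t id) { return ox + ((id / H) % W + 0.5) * sx; };
  auto py = [&](size_t id) { return oy + (id % H + 0.5) * sy; };
  auto pz = [&](size_t id) { return oz + (id / ((size_t)H * W) + 0.5) * sz; };

  size_t g[8];
  double val[8];

  auto vertex_on = [&](int ca, int cb) -> int {
    size_t ga = g[ca], gb = g[cb];
    double va = val[ca], vb = val[cb];
    uint64_t key = ga < gb ? (uint64_t)ga * ((uint64_t)H * W * Z) + gb
                           : (uint64_t)gb * ((uint64_t)H * W * Z) + ga;
    auto it = acc.edgemap.find(key);
    if (it != acc.edgemap.end()) return it->second;
    double t = (vb != va) ? (iso - va) / (vb - va) : 0.5;
    t = clampd(t, 1e-6, 1.0 - 1e-6);
    acc.verts.push_back(px(ga) + t * (px(gb) - px(ga)));
    acc.verts.push_back(py(ga) + t * (py(gb) - py(ga)));
    acc.verts.push_back(pz(ga) + t * (pz(gb) - pz(ga)));
    int id = acc.verts.size() / 3 - 1;
    acc.edgemap.emplace(key, id);
    return id;
  };

  auto emit = [&](int a, int b, int c, const double *inpt) {
    if (a == b || b == c || a == c) return;
    double *V = acc.verts.data();
    double e1[3] = {V[3*b]-V[3*a], V[3*b+1]-V[3*a+1], V[3*b+2]-V[3*a+2]};
    double e2[3] = {V[3*c]-V[3*a], V[3*c+1]-V[3*a+1], V[3*c+2]-V[3*a+2]};
    double n[3] = {e1[1]*e2[2]-e1[2]*e2[1], e1[2]*e2[0]-e1[0]*e2[2],
                   e1[0]*e2[1]-e1[1]*e2[0]};
    double d[3] = {(V[3*a]+V[3*b]+V[3*c])/3.0 - inpt[0],
                   (V[3*a+1]+V[3*b+1]+V[3*c+1])/3.0 - inpt[1],
                   (V[3*a+2]+V[3*b+2]+V[3*c+2])/3.0 - inpt[2]};
    if (n[0]*d[0] + n[1]*d[1] + n[2]*d[2] < 0) std::swap(b, c);
    acc.faces.push_back(a); acc.faces.push_back(b); acc.faces.push_back(c);
  };

  for (int iz = 0; iz + 1 < Z; ++iz) {
    for (int ix = 0; ix + 1 < W; ++ix) {
      for (int iy = 0; iy + 1 < H; ++iy) {
        int cs = 0;
        for (int c = 0; c < 8; ++c) {
          int cx = ix + (c & 1), cy = iy + ((c >> 1) & 1), cz = iz + ((c >> 2) & 1);
          g[c] = (size_t)cy + (size_t)H * (cx + (size_t)W * cz);
          val[c] = getv(g[c]);
          if (val[c] >= iso) cs |= (1 << c);
        }
        if (cs == 0 || cs == 255) continue;
        // inside reference point for orientation
        double ref[3] = {0, 0, 0};
        int nin = 0;
        for (int c = 0; c < 8; ++c)
          if ((cs >> c) & 1) {
            ref[0] += px(g[c]); ref[1] += py(g[c]); ref[2] += pz(g[c]);
            nin++;
          }
        ref[0] /= nin; ref[1] /= nin; ref[2] /= nin;
        for (const auto &cyc : CT.poly[cs]) {
          std::vector<int> vid(cyc.size());
          for (size_t i = 0; i < cyc.size(); ++i)
            vid[i] = vertex_on(cyc[i] / 8, cyc[i] % 8);
          if (cyc.size() == 3) {
            emit(vid[0], vid[1], vid[2], ref);
          } else {
            // star-triangulate from the polygon centroid: spokes are private
            // to this patch, so no triangle edge can collide with a
            // neighboring cube's triangulation of the shared face
            double cx = 0, cy = 0, cz = 0;
            for (int v : vid) {
              cx += acc.verts[3 * v]; cy += acc.verts[3 * v + 1];
              cz += acc.verts[3 * v + 2];
            }
            acc.verts.push_back(cx / vid.size());
            acc.verts.push_back(cy / vid.size());
            acc.verts.push_back(cz / vid.size());
            int cid = acc.verts.size() / 3 - 1;
            for (size_t i = 0; i < cyc.size(); ++i)
              emit(cid, vid[i], vid[(i + 1) % cyc.size()], ref);
          }
        }
      }
    }
  }
}

static List mt_result(MTAcc &acc) {
  int nv = acc.verts.size() / 3, nf = acc.faces.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) V(i, j) = acc.verts[3 * i + j];
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i)
    for (int j = 0; j < 3; ++j) F(i, j) = acc.faces[3 * i + j] + 1;
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// [[Rcpp::export]]
List cpp_isosurface(NumericVector vol, double iso, NumericVector spacing,
                    NumericVector origin) {
  IntegerVector dm = vol.attr("dim");
  MTAcc acc;
  const double *p = &vol[0];
  march([p](size_t i) { return p[i]; }, dm[0], dm[1], dm[2], iso,
        spacing[0], spacing[1], spacing[2], origin[0], origin[1], origin[2], acc);
  return mt_result(acc);
}

// [[Rcpp::export]]
List cpp_isosurface_raw(RawVector vol, IntegerVector dims, double iso,
                        NumericVector spacing, NumericVector origin) {
  MTAcc acc;
  const Rbyte *p = &vol[0];
  march([p](size_t i) { return (double)p[i]; }, dims[0], dims[1], dims[2], iso,
        spacing[0], spacing[1], spacing[2], origin[0], origin[1], origin[2], acc);
  return mt_result(acc);
}
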