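#include "splenvas.h"
#include <queue>
#include <tuple>
#include <array>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

// Quadric-error-metric edge-collapse decimation (Garland-Heckbert).  Collapse
// placement is the best of {u, v, midpoint} under the summed quadric; a
// collapse is rejected if it would break the link condition (pinch the mesh
// into a non-manifold edge) or flip/degenerate a surviving face.

typedef std::array<double, 10> Quad;  // symmetric 4x4, row-major upper part

static inline void quad_add(Quad &a, const Quad &b) {
  for (int i = 0; i < 10; ++i) a[i] += b[i];
}

static inline double quad_cost(const Quad &q, const double *p) {
  double x = p[0], y = p[1], z = p[2];
  return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x
       + q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y
       + q[7]*z*z + 2*q[8]*z
       + q[9];
}

// [[Rcpp::export]]
List cpp_quadric_decimate(NumericMatrix verts, IntegerMatrix faces,
                          int target_faces) {
  int nv = verts.nrow(), nf = faces.nrow();
  std::vector<std::array<double, 3>> P(nv);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) P[i][j] = verts(i, j);
  std::vector<std::array<int, 3>> F(nf);
  for (int f = 0; f < nf; ++f)
    for (int j = 0; j < 3; ++j) F[f][j] = faces(f, j) - 1;
  std::vector<char> valive(nv, 1), falive(nf, 1);
  std::vector<std::vector<int>> vf(nv);
  for (int f = 0; f < nf; ++f)
    for (int j = 0; j < 3; ++j) vf[F[f][j]].push_back(f);

  auto face_normal = [&](int f, double *n) {
    const auto &a = P[F[f][0]], &b = P[F[f][1]], &c = P[F[f][2]];
    double e1[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
    double e2[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
    n[0] = e1[1]*e2[2]-e1[2]*e2[1];
    n[1] = e1[2]*e2[0]-e1[0]*e2[2];
    n[2] = e1[0]*e2[1]-e1[1]*e2[0];
    return 0.5 * std::sqrt(n[0]*n[0]+n[1]*n[1]+n[2]*n[2]);  // area
  };

  std::vector<Quad> Q(nv);
  for (auto &q : Q) q.fill(0.0);
  for (int f = 0; f < nf; ++f) {
    double n[3];
    double area = face_normal(f, n);
    double len = 2 * area;
    if (len <= 0) continue;
    for (int j = 0; j < 3; ++j) n[j] /= len;
    const auto &a = P[F[f][0]];
    double d = -(n[0]*a[0] + n[1]*a[1] + n[2]*a[2]);
    Quad k = {n[0]*n[0], n[0]*n[1], n[0]*n[2], n[0]*d,
              n[1]*n[1], n[1]*n[2], n[1]*d,
              n[2]*n[2], n[2]*d, d*d};
    for (int i = 0; i < 10; ++i) k[i] *= area;
    for (int j = 0; j < 3; ++j) quad_add(Q[F[f][j]], k);
  }

  std::vector<unsigned> stamp(nv, 0);
  typedef std::tuple<double, int, int, unsigned, unsigned> HE;
  std::priority_queue<HE, std::vector<HE>, std::greater<HE>> heap;

  auto edge_cost = [&](int u, int v, double *pos) {
    Quad q = Q[u];
    quad_add(q, Q[v]);
    double mid[3] = {(P[u][0]+P[v][0])/2, (P[u][1]+P[v][1])/2, (P[u][2]+P[v][2])/2};
    double cu = quad_cost(q, P[u].data());
    double cv = quad_cost(q, P[v].data());
    double cm = quad_cost(q, mid);
    if (cu <= cv && cu <= cm) { std::copy(P[u].begin(), P[u].end(), pos); return cu; }
    if (cv <= cm) { std::copy(P[v].begin(), P[v].end(), pos); return cv; }
    std::copy(mid, mid + 3, pos); return cm;
  };

  {
    std::unordered_set<uint64_t> seen;
    for (int f = 0; f < nf; ++f)
      for (int e = 0; e < 3; ++e) {
        int a = F[f][e], b = F[f][(e + 1) % 3];
        uint64_t key = a < b ? ((uint64_t)a << 32) | b : ((uint64_t)b << 32) | a;
        if (!seen.insert(key).second) continue;
        double pos[3];
        double c = edge_cost(a, b, pos);
        heap.emplace(c, std::min(a, b), std::max(a, b), stamp[a < b ? a : b], stamp[a < b ? b : a]);
      }
  }

  auto vneighbors = [&](int u) {
    std::vector<int> nb;
    for (int f : vf[u]) {
      if (!falive[f]) continue;
      for (int j = 0; j < 3; ++j)
        if (F[f][j] != u) nb.push_back(F[f][j]);
    }
    std::sort(nb.begin(), nb.end());
    nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    return nb;
  };

  int alive_faces = nf;
  while (alive_faces > target_faces && !heap.empty()) {
    auto [cost, u, v, su, sv] = heap.top();
    heap.pop();
    if (!valive[u] || !valive[v]) continue;
    if (stamp[u] != su || stamp[v] != sv) continue;

    // shared faces and link condition
    std::vector<int> shared, opp;
    for (int f : vf[u]) {
      if (!falive[f]) continue;
      bool hasv = false;
      int other = -1;
      for (int j = 0; j < 3; ++j) {
        if (F[f][j] == v) hasv = true;
        else if (F[f][j] != u) other = F[f][j];
      }
      if (hasv) { shared.push_back(f); opp.push_back(other); }
    }
    if (shared.empty()) continue;  // edge no longer exists
    std::vector<int> nu = vneighbors(u), nvv = vneighbors(v), common;
    std::set_intersection(nu.begin(), nu.end(), nvv.begin(), nvv.end(),
                          std::back_inserter(common));
    if (common.size() != shared.size()) continue;  // would pinch: reject

    double pos[3];
    edge_cost(u, v, pos);

    // flip / degeneracy audit on surviving faces
    bool ok = true;
    std::array<double, 3> oldu = P[u], oldv = P[v];
    for (int pass = 0; pass < 2 && ok; ++pass) {
      int w = pass == 0 ? u : v;
      for (int f : vf[w]) {
        if (!falive[f]) continue;
        bool dies = false;
        for (size_t s = 0; s < shared.size(); ++s) if (shared[s] == f) dies = true;
        if (dies) continue;
        double n0[3], n1[3];
        double a0 = face_normal(f, n0);
        P[u] = {pos[0], pos[1], pos[2]};
        P[v] = {pos[0], pos[1], pos[2]};
        double a1 = face_normal(f, n1);
        P[u] = oldu; P[v] = oldv;
        if (a1 < 1e-12 || (n0[0]*n1[0] + n0[1]*n1[1] + n0[2]*n1[2]) <= 0) {
          ok = false; break;
        }
        (void)a0;
      }
    }
    if (!ok) continue;

    // commit: v merges into u at pos
    P[u] = {pos[0], pos[1], pos[2]};
    quad_add(Q[u], Q[v]);
    valive[v] = 0;
    for (int f : shared) {
      if (falive[f]) { falive[f] = 0; alive_faces--; }
    }
    for (int f : vf[v]) {
      if (!falive[f]) continue;
      for (int j = 0; j < 3; ++j)
        if (F[f][j] == v) F[f][j] = u;
      vf[u].push_back(f);
    }
    vf[v].clear();
    stamp[u]++; stamp[v]++;
    for (int w : vneighbors(u)) {
      double p2[3];
      double c = edge_cost(u, w, p2);
      heap.emplace(c, std::min(u, w), std::max(u, w),
                   stamp[std::min(u, w)], stamp[std::max(u, w)]);
    }
  }

  // compact
  std::vector<int> newid(nv, -1);
  int nnv = 0;
  for (int f = 0; f < nf; ++f)
    if (falive[f])
      for (int j = 0; j < 3; ++j)
        if (newid[F[f][j]] < 0) newid[F[f][j]] = nnv++;
  NumericMatrix V(nnv, 3);
  for (int i = 0; i < nv; ++i)
    if (newid[i] >= 0)
      for (int j = 0; j < 3; ++j) V(newid[i], j) = P[i][j];
  int nnf = 0;
  for (int f = 0; f < nf; ++f) nnf += falive[f] ? 1 : 0;
  IntegerMatrix FO(nnf, 3);
  int fi = 0;
  for (int f = 0; f < nf; ++f) {
    if (!falive[f]) continue;
    for (int j = 0; j < 3; ++j) FO(fi, j) = newid[F[f][j]] + 1;
    fi++;
  }
  return List::create(_["vertices"] = V, _["faces"] = FO);
}
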