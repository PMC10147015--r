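#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// 3D convex hull, quickhull style: always insert the point furthest outside
// the current hull, delete the BFS-connected region of faces visible from it
// (coplanar neighbours merged in), and refill the horizon cycle. The
// furthest-first order and connected visible region keep the horizon a
// simple closed cycle, so face counts stay O(hull size) and termination is
// guaranteed (each iteration consumes one point). Degenerate inputs
// (collinear / coplanar within tolerance) fall back to a planar hull:
// volume 0, area of the flat polygon, degenerate flag set.

struct Face { int a, b, c; bool alive; };

static inline void sub3(const double *p, const double *q, double *r) {
  r[0] = p[0] - q[0]; r[1] = p[1] - q[1]; r[2] = p[2] - q[2];
}
static inline void cross3(const double *u, const double *v, double *w) {
  w[0] = u[1] * v[2] - u[2] * v[1];
  w[1] = u[2] * v[0] - u[0] * v[2];
  w[2] = u[0] * v[1] - u[1] * v[0];
}
static inline double dot3(const double *u, const double *v) {
  return u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
}

// 6 x signed volume of tetra (a,b,c,d)
static double orient(const double *a, const double *b, const double *c,
                     const double *d) {
  double u[3], v[3], w[3], n[3];
  sub3(b, a, u); sub3(c, a, v); sub3(d, a, w);
  cross3(u, v, n);
  return dot3(n, w);
}

// signed distance of d from the plane of (a,b,c), positive on the outward
// (right-hand) side; better conditioned than the raw orient volume
static double planeDist(const double *a, const double *b, const double *c,
                        const double *d) {
  double u[3], v[3], w[3], n[3];
  sub3(b, a, u); sub3(c, a, v); sub3(d, a, w);
  cross3(u, v, n);
  double nl = std::sqrt(dot3(n, n));
  if (nl == 0.0) return 0.0;
  return dot3(n, w) / nl;
}

// [[Rcpp::export]]
List cpp_convex_hull3(NumericMatrix pts) {
  int n0 = pts.nrow();
  std::vector<std::array<double,3> > P;
  P.reserve(n0);
  for (int i = 0; i < n0; i++) {
    std::array<double,3> p = {pts(i,0), pts(i,1), pts(i,2)};
    bool dup = false;
    for (auto &q : P) if (q == p) { dup = true; break; }
    if (!dup) P.push_back(p);
  }
  int n = (int)P.size();

  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (auto &p : P) for (int d = 0; d < 3; d++) {
    lo[d] = std::min(lo[d], p[d]); hi[d] = std::max(hi[d], p[d]);
  }
  double scale = std::max({hi[0]-lo[0], hi[1]-lo[1], hi[2]-lo[2], 1e-12});
  const double tolD = 1e-9 * scale;   // plane-distance tolerance

  auto planar_result = [&]() -> List {
    double area = 0.0;
    if (n >= 3) {
      double cen[3] = {0,0,0};
      for (auto &p : P) for (int d = 0; d < 3; d++) cen[d] += p[d] / n;
      double bestn[3] = {0,0,0}; double bestlen = 0.0;
      for (int i = 1; i < n; i++) for (int j = i+1; j < n; j++) {
        double u[3], v[3], w[3];
        sub3(P[i].data(), P[0].data(), u);
        sub3(P[j].data(), P[0].data(), v);
        cross3(u, v, w);
        double l = dot3(w, w);
        if (l > bestlen) { bestlen = l; std::copy(w, w+3, bestn); }
      }
      if (bestlen > 0) {
        double nl = std::sqrt(bestlen);
        for (int d = 0; d < 3; d++) bestn[d] /= nl;
        double ax[3] = {1,0,0};
        if (std::fabs(bestn[0]) > 0.9) { ax[0] = 0; ax[1] = 1; }
        double e1[3], e2[3];
        cross3(bestn, ax, e1);
        double l1 = std::sqrt(dot3(e1,e1));
        for (int d = 0; d < 3; d++) e1[d] /= l1;
        cross3(bestn, e1, e2);
        std::vector<std::pair<double,double> > q(n);
        for (int i = 0; i < n; i++) {
          double r[3]; sub3(P[i].data(), cen, r);
          q[i] = std::make_pair(dot3(r, e1), dot3(r, e2));
        }
        std::sort(q.begin(), q.end());
        q.erase(std::unique(q.begin(), q.end()), q.end());
        int m = (int)q.size();
        if (m >= 3) {
          std::vector<std::pair<double,double> > h(2 * m);
          int k = 0;
          auto cr = [](const std::pair<double,double>&O,
                       const std::pair<double,double>&A,
                       const std::pair<double,double>&B) {
            return (A.first-O.first)*(B.second-O.second) -
                   (A.second-O.second)*(B.first-O.first);
          };
          for (int i = 0; i < m; i++) {
            while (k >= 2 && cr(h[k-2], h[k-1], q[i]) <= 0) k--;
            h[k++] = q[i];
          }
          for (int i = m - 2, t = k + 1; i >= 0; i--) {
            while (k >= t && cr(h[k-2], h[k-1], q[i]) <= 0) k--;
            h[k++] = q[i];
          }
          h.resize(k - 1);
          for (size_t i = 0; i < h.size(); i++) {
            size_t j = (i + 1) % h.size();
            area += h[i].first * h[j].second - h[j].first * h[i].second;
          }
          area = std::fabs(area) / 2.0;
        }
      }
    }
    return List::create(_["volume"] = 0.0, _["area"] = area,
                        _["degenerate"] = true);
  };

  if (n < 4) return planar_result();

  // initial tetrahedron: extreme pair, then max-area, then max-volume
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = 0.0;
  for (int d = 0; d < 3; d++) {   // spread across the widest axis
    if (hi[d] - lo[d] == scale) {
      double blo = R_PosInf, bhi = R_NegInf;
      for (int i = 0; i < n; i++) {
        if (P[i][d] < blo) { blo = P[i][d]; i0 = i; }
        if (P[i][d] > bhi) { bhi = P[i][d]; i1 = i; }
      }
      break;
    }
  }
  if (i1 < 0 || i1 == i0) return planar_result();
  best = 0.0;
  for (int i = 0; i < n; i++) {
    if (i == i0 || i == i1) continue;
    double u[3], v[3], w[3];
    sub3(P[i1].data(), P[i0].data(), u);
    sub3(P[i].data(), P[i0].data(), v);
    cross3(u, v, w);
    double l = dot3(w, w);
    if (l > best) { best = l; i2 = i; }
  }
  if (i2 < 0 || best == 0.0) return planar_result();
  best = 0.0;
  for (int i = 0; i < n; i++) {
    if (i == i0 || i == i1 || i == i2) continue;
    double v = std::fabs(planeDist(P[i0].data(), P[i1].data(), P[i2].data(),
                                   P[i].data()));
    if (v > best) { best = v; i3 = i; }
  }
  if (i3 < 0 || best <= tolD) return planar_result();

  std::vector<Face> faces;
  faces.reserve(8 * (size_t)std::min(n, 1024));
  double cen0[3];
  for (int d = 0; d < 3; d++)
    cen0[d] = (P[i0][d] + P[i1][d] + P[i2][d] + P[i3][d]) / 4.0;
  auto addface = [&](int a, int b, int c) {
    if (orient(P[a].data(), P[b].data(), P[c].data(), cen0) > 0)
      std::swap(b, c);
    faces.push_back(Face{a, b, c, true});
  };
  addface(i0, i1, i2);
  addface(i0, i1, i3);
  addface(i0, i2, i3);
  addface(i1, i2, i3);

  std::vector<bool> used(n, false);
  used[i0] = used[i1] = used[i2] = used[i3] = true;
  std::vector<int> pending;
  for (int i = 0; i < n; i++) if (!used[i]) pending.push_back(i);

  auto fdist = [&](const Face &f, int p) {
    return planeDist(P[f.a].data(), P[f.b].data(), P[f.c].data(),
                     P[p].data());
  };

  // at most n iterations: each inserts one point as a hull vertex
  for (int iter = 0; iter < n && !pending.empty(); iter++) {
    // furthest pending point over all alive faces
    int bestP = -1, bestF = -1;
    double bestD = tolD;
    std::vector<int> stillOut;
    stillOut.reserve(pending.size());
    for (int p : pending) {
      double dmax = -R_PosInf; int fmax = -1;
      for (size_t f = 0; f < faces.size(); f++) {
        if (!faces[f].alive) continue;
        double d = fdist(faces[f], p);
        if (d > dmax) { dmax = d; fmax = (int)f; }
      }
      if (dmax > tolD) {
        stillOut.push_back(p);
        if (dmax > bestD) { bestD = dmax; bestP = p; bestF = fmax; }
      }
    }
    pending = stillOut;
    if (bestP < 0) break;

    // adjacency over alive faces via directed edge map
    std::map<std::pair<int,int>, int> edgeFace;
    for (size_t f = 0; f < faces.size(); f++) {
      if (!faces[f].alive) continue;
      const Face &F = faces[f];
      edgeFace[std::make_pair(F.a, F.b)] = (int)f;
      edgeFace[std::make_pair(F.b, F.c)] = (int)f;
      edgeFace[std::make_pair(F.c, F.a)] = (int)f;
    }
    auto neighbour = [&](int f, int eidx) -> int {
      const Face &F = faces[f];
      int u = eidx == 0 ? F.b : (eidx == 1 ? F.c : F.a);
      int v = eidx == 0 ? F.a : (eidx == 1 ? F.b : F.c);
      auto it = edgeFace.find(std::make_pair(u, v));
      return it == edgeFace.end() ? -1 : it->second;
    };

    // BFS-connected visible region from the best face; coplanar neighbours
    // (distance > -tolD) are merged in so no sliver faces survive
    std::vector<int> vis;
    std::vector<char> inVis(faces.size(), 0);
    vis.push_back(bestF); inVis[bestF] = 1;
    for (size_t qi = 0; qi < vis.size(); qi++) {
      int f = vis[qi];
      for (int e = 0; e < 3; e++) {
        int g = neighbour(f, e);
        if (g < 0 || inVis[g]) continue;
        if (fdist(faces[g], bestP) > -tolD) { vis.push_back(g); inVis[g] = 1; }
      }
    }

    // horizon: directed edges of visible faces whose reverse edge belongs
    // to a non-visible alive face
    std::vector<std::pair<int,int> > horizon;
    for (int f : vis) {
      const Face &F = faces[f];
      int E[3][2] = {{F.a, F.b}, {F.b, F.c}, {F.c, F.a}};
      for (auto &ed : E) {
        auto it = edgeFace.find(std::make_pair(ed[1], ed[0]));
        if (it == edgeFace.end() || !inVis[it->second])
          horizon.push_back(std::make_pair(ed[0], ed[1]));
      }
    }
    for (int f : vis) faces[f].alive = false;
    for (auto &ed : horizon) addface(ed.first, ed.second, bestP);
    used[bestP] = true;
  }

  double vol = 0.0, area = 0.0;
  for (auto &f : faces) {
    if (!f.alive) continue;
    double u[3], v[3], w[3];
    sub3(P[f.b].data(), P[f.a].data(), u);
    sub3(P[f.c].data(), P[f.a].data(), v);
    cross3(u, v, w);
    area += 0.5 * std::sqrt(dot3(w, w));
    vol += orient(P[f.a].data(), P[f.b].data(), P[f.c].data(), cen0) / 6.0;
  }
  vol = std::fabs(vol);
  return List::create(_["volume"] = vol, _["area"] = area,
                      _["degenerate"] = false);
}
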