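#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_map>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Quickhull in 3D. Returns triangular facets (1-based indices into the input
// points) with outward orientation, plus the hull vertex index set.

namespace {

struct Face {
  int a, b, c;             // CCW from outside
  double n[3], off;        // plane: n . x = off, |n| = 1
  int nab, nbc, nca;       // neighbor face across each directed edge
  std::vector<int> outside;
  bool alive;
};

struct Hull {
  const double* P;
  int n;
  double eps;
  std::vector<Face> faces;
  double inner[3];  // interior reference point

  double* pt(int i, double* buf) const { return buf; }
  inline double px(int i) const { return P[i]; }
  inline double py(int i) const { return P[i + n]; }
  inline double pz(int i) const { return P[i + 2 * n]; }

  // plane from the vertex order alone; orientation is combinatorial
  // (inherited from the horizon edge direction), never flipped numerically,
  // so directed-edge adjacency stays consistent even for sliver faces
  void plane(Face& f) {
    double ux = px(f.b) - px(f.a), uy = py(f.b) - py(f.a), uz = pz(f.b) - pz(f.a);
    double vx = px(f.c) - px(f.a), vy = py(f.c) - py(f.a), vz = pz(f.c) - pz(f.a);
    f.n[0] = uy * vz - uz * vy;
    f.n[1] = uz * vx - ux * vz;
    f.n[2] = ux * vy - uy * vx;
    double l = std::sqrt(f.n[0]*f.n[0] + f.n[1]*f.n[1] + f.n[2]*f.n[2]);
    if (l > 0) { f.n[0] /= l; f.n[1] /= l; f.n[2] /= l; }
    f.off = f.n[0]*px(f.a) + f.n[1]*py(f.a) + f.n[2]*pz(f.a);
  }

  // initial faces only: orient outward with respect to the interior point
  void orient_init(Face& f) {
    plane(f);
    double d = f.n[0]*inner[0] + f.n[1]*inner[1] + f.n[2]*inner[2] - f.off;
    if (d > 0) {
      std::swap(f.b, f.c);
      plane(f);
    }
  }

  inline double dist(const Face& f, int i) const {
    return f.n[0]*px(i) + f.n[1]*py(i) + f.n[2]*pz(i) - f.off;
  }
};

}  // namespace

// [[Rcpp::export(name = ".quickhull3")]]
List quickhull3(NumericMatrix pts, double tol) {
  int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  Hull H;
  H.P = REAL(pts);
  H.n = n;

  // bounding box and scale
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = std::numeric_limits<double>::infinity(); hi[d] = -lo[d]; }
  for (int i = 0; i < n; ++i) {
    double c[3] = {H.px(i), H.py(i), H.pz(i)};
    for (int d = 0; d < 3; ++d) { lo[d] = std::min(lo[d], c[d]); hi[d] = std::max(hi[d], c[d]); }
  }
  double diag = std::sqrt((hi[0]-lo[0])*(hi[0]-lo[0]) + (hi[1]-lo[1])*(hi[1]-lo[1]) +
                          (hi[2]-lo[2])*(hi[2]-lo[2]));
  if (diag <= 0) stop("degenerate point set: all points identical");
  H.eps = (tol > 0 ? tol : 1e-10) * diag;

  // initial simplex: extremes along the longest axis
  int ax = 0;
  for (int d = 1; d < 3; ++d) if (hi[d] - lo[d] > hi[ax] - lo[ax]) ax = d;
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    double c = (ax == 0 ? H.px(i) : ax == 1 ? H.py(i) : H.pz(i));
    double c0 = (ax == 0 ? H.px(i0) : ax == 1 ? H.py(i0) : H.pz(i0));
    double c1 = (ax == 0 ? H.px(i1) : ax == 1 ? H.py(i1) : H.pz(i1));
    if (c < c0) i0 = i;
    if (c > c1) i1 = i;
  }
  if (i0 == i1) stop("degenerate point set: all points identical");
  // farthest from line i0-i1
  double ux = H.px(i1)-H.px(i0), uy = H.py(i1)-H.py(i0), uz = H.pz(i1)-H.pz(i0);
  double ul2 = ux*ux + uy*uy + uz*uz;
  int i2 = -1; double best = H.eps;
  for (int i = 0; i < n; ++i) {
    double wx = H.px(i)-H.px(i0), wy = H.py(i)-H.py(i0), wz = H.pz(i)-H.pz(i0);
    double t = (wx*ux + wy*uy + wz*uz) / ul2;
    double dx = wx - t*ux, dy = wy - t*uy, dz = wz - t*uz;
    double d = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) stop("degenerate point set: points are collinear");
  // farthest from plane i0,i1,i2
  double vx = H.px(i2)-H.px(i0), vy = H.py(i2)-H.py(i0), vz = H.pz(i2)-H.pz(i0);
  double nx = uy*vz - uz*vy, ny = uz*vx - ux*vz, nz = ux*vy - uy*vx;
  double nl = std::sqrt(nx*nx + ny*ny + nz*nz);
  nx /= nl; ny /= nl; nz /= nl;
  double off = nx*H.px(i0) + ny*H.py(i0) + nz*H.pz(i0);
  int i3 = -1; best = H.eps;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(nx*H.px(i) + ny*H.py(i) + nz*H.pz(i) - off);
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) stop("degenerate point set: points are coplanar");

  H.inner[0] = (H.px(i0)+H.px(i1)+H.px(i2)+H.px(i3)) / 4.0;
  H.inner[1] = (H.py(i0)+H.py(i1)+H.py(i2)+H.py(i3)) / 4.0;
  H.inner[2] = (H.pz(i0)+H.pz(i1)+H.pz(i2)+H.pz(i3)) / 4.0;

  // initial tetra faces; neighbor links by shared edges set below
  auto mkface = [&](int a, int b, int c) {
    Face f; f.a = a; f.b = b; f.c = c; f.nab = f.nbc = f.nca = -1;
    f.alive = true; H.orient_init(f); H.faces.push_back(f);
  };
  mkface(i0, i1, i2); mkface(i0, i1, i3); mkface(i0, i2, i3); mkface(i1, i2, i3);

  // Pair faces across shared edges by matching opposite directed edges;
  // links are only overwritten on a match, so edges from `fset` faces to
  // faces outside the set keep their existing (still valid) links. Directed
  // matching also stays consistent when the horizon pinches at a vertex.
  auto pair_edges = [&](const std::vector<int>& fset) {
    std::unordered_map<long long, std::pair<int,int>> em;  // directed edge
    for (int fi : fset) {
      Face& f = H.faces[fi];
      if (!f.alive) continue;
      int vs[3] = {f.a, f.b, f.c};
      for (int s = 0; s < 3; ++s) {
        int u = vs[s], v = vs[(s+1)%3];
        long long mate = (long long)v * n + u;
        auto it = em.find(mate);
        if (it != em.end()) {
          int gi = it->second.first, gs = it->second.second;
          int* fn = (s==0 ? &f.nab : s==1 ? &f.nbc : &f.nca);
          Face& g = H.faces[gi];
          int* gn = (gs==0 ? &g.nab : gs==1 ? &g.nbc : &g.nca);
          *fn = gi; *gn = fi;
          em.erase(it);
        } else {
          em[(long long)u * n + v] = {fi, s};
        }
      }
    }
  };
  pair_edges({0, 1, 2, 3});

  // assign points
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (auto& f : H.faces)
      if (H.dist(f, i) > H.eps) { f.outside.push_back(i); break; }
  }

  std::vector<int> pending;
  for (int fi = 0; fi < (int)H.faces.size(); ++fi)
    if (!H.faces[fi].outside.empty()) pending.push_back(fi);

  long long guard = 0, guard_max = 50LL * n + 1000;
  while (!pending.empty()) {
    if (++guard > guard_max) stop("convex hull failed to converge");
    int fi = pending.back(); pending.pop_back();
    Face& f0 = H.faces[fi];
    if (!f0.alive || f0.outside.empty()) continue;
    // furthest point
    int p = -1; double best = -1;
    for (int i : f0.outside) {
      double d = H.dist(f0, i);
      if (d > best) { best = d; p = i; }
    }
    // visible set via DFS over neighbors
    std::vector<int> visible, stack = {fi};
    std::vector<char> seen(H.faces.size(), 0);
    seen[fi] = 1;
    while (!stack.empty()) {
      int gi = stack.back(); stack.pop_back();
      visible.push_back(gi);
      Face& g = H.faces[gi];
      for (int nb : {g.nab, g.nbc, g.nca}) {
        if (nb < 0 || seen[nb] || !H.faces[nb].alive) continue;
        // faces coplanar with the apex (within eps) are absorbed into the
        // visible region so the horizon always sits on strictly-below
        // faces; leaving them in place creates sliver topology
        if (H.dist(H.faces[nb], p) > -H.eps) { seen[nb] = 1; stack.push_back(nb); }
      }
    }
    // horizon: directed edges of visible faces whose neighbor is not visible
    struct HEdge { int u, v, nb; };
    std::vector<HEdge> horizon;
    std::vector<int> orphan;
    for (int gi : visible) {
      Face& g = H.faces[gi];
      int vs[3] = {g.a, g.b, g.c};
      int nbs[3] = {g.nab, g.nbc, g.nca};
      for (int s = 0; s < 3; ++s) {
        int nb = nbs[s];
        if (nb >= 0 && !seen[nb]) horizon.push_back({vs[s], vs[(s+1)%3], nb});
      }
      for (int i : g.outside) if (i != p) orphan.push_back(i);
      g.alive = false;
      g.outside.clear();
    }
    if (horizon.empty()) stop("convex hull failed: empty horizon");
    // new faces (u, v, p); adjacency is rebuilt from scratch below, which
    // stays correct even when the horizon pinches at a vertex
    std::vector<int> newf, affected;
    for (auto& e : horizon) {
      Face nf2; nf2.a = e.u; nf2.b = e.v; nf2.c = p;
      nf2.nab = -1; nf2.nbc = -1; nf2.nca = -1; nf2.alive = true;
      H.plane(nf2);
      int id = (int)H.faces.size();
      H.faces.push_back(nf2);
      newf.push_back(id);
      affected.push_back(id);
      affected.push_back(e.nb);
    }
    pair_edges(affected);
    // reassign orphans
    for (int i : orphan) {
      for (int id : newf) {
        if (H.dist(H.faces[id], i) > H.eps) { H.faces[id].outside.push_back(i); break; }
      }
    }
    for (int id : newf)
      if (!H.faces[id].outside.empty()) pending.push_back(id);
  }

  std::vector<int> keep;
  for (int fi = 0; fi < (int)H.faces.size(); ++fi)
    if (H.faces[fi].alive) keep.push_back(fi);
  {
    // verify the facet surface is closed: every undirected edge twice
    std::unordered_map<long long, int> ec;
    for (int fi : keep) {
      Face& f = H.faces[fi];
      int vs[3] = {f.a, f.b, f.c};
      for (int s2 = 0; s2 < 3; ++s2) {
        int u = vs[s2], v = vs[(s2+1)%3];
        ec[(long long)std::min(u,v) * n + std::max(u,v)] += 1;
      }
    }
    for (auto& kv : ec)
      if (kv.second != 2)
        stop("convex hull construction lost closure (tolerance too tight "
             "for this input); retry with a larger tol");
  }
  IntegerMatrix F((int)keep.size(), 3);
  std::vector<char> used(n, 0);
  for (int r = 0; r < (int)keep.size(); ++r) {
    Face& f = H.faces[keep[r]];
    F(r, 0) = f.a + 1; F(r, 1) = f.b + 1; F(r, 2) = f.c + 1;
    used[f.a] = used[f.b] = used[f.c] = 1;
  }
  std::vector<int> vs;
  for (int i = 0; i < n; ++i) if (used[i]) vs.push_back(i + 1);
  return List::create(_["faces"] = F, _["vertex_index"] = IntegerVector(vs.begin(), vs.end()),
                      _["eps"] = H.eps);
}
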