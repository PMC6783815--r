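#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// dim = c(nz, ny, nx); linear = z + nz*(y + ny*x)

// Separable Gaussian smoothing with zero (background) boundary condition.
// [[Rcpp::export(name = ".gaussian_smooth3d")]]
NumericVector gaussian_smooth3d(NumericVector vol, double sigma) {
  IntegerVector dim = vol.attr("dim");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  if (sigma <= 0) return clone(vol);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (auto& v : k) v /= s;

  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  const int n[3] = {nz, ny, nx};
  const int stride[3] = {1, nz, nz * ny};
  for (int axis = 0; axis < 3; ++axis) {
    int len = n[axis], st = stride[axis];
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          int idx[3] = {z, y, x};
          int pos = idx[axis];
          int base = z + nz * (y + ny * x);
          double acc = 0;
          int lo = std::max(-r, -pos), hi = std::min(r, len - 1 - pos);
          for (int i = lo; i <= hi; ++i) acc += k[i + r] * a[base + i * st];
          b[base] = acc;
        }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Marching tetrahedra on the Kuhn (6-tet, face-consistent) decomposition of
// each grid cell. Inside = value > level. Vertices are welded by the grid
// edge (node pair) they sit on, so the mesh is watertight by construction.
// Coordinates are 0-based node indices in (z, y, x) order.
// [[Rcpp::export(name = ".marching_tets")]]
List marching_tets(NumericVector vol, double level) {
  IntegerVector dim = vol.attr("dim");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  auto lin = [&](int z, int y, int x) { return (long long)z + (long long)nz * (y + (long long)ny * x); };

  // 6 permutations of axis step order (axes: 0=z,1=y,2=x)
  static const int perms[6][3] = {
    {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}
  };

  std::unordered_map<long long, int> vmap;  // edge key -> vertex index
  std::vector<double> vx, vy, vz;           // vertex coords (x,y,z order kept as z,y,x cols later)
  std::vector<int> f0, f1, f2;

  const double* f = REAL(vol);

  auto vertex_on = [&](long long na, long long nb, const int ca[3], const int cb[3]) {
    long long a = na, b = nb;
    const int *pa = ca, *pb = cb;
    if (a > b) { std::swap(a, b); std::swap(pa, pb); }
    long long key = a * (long long)(nz) * ny * nx + b;  // unique ordered pair key
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double fa = f[a], fb = f[b];
    double t = (level - fa) / (fb - fa);
    int id = (int)vz.size();
    vz.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vx.push_back(pa[2] + t * (pb[2] - pa[2]));
    vmap.emplace(key, id);
    return id;
  };

  int corner[4][3];     // tet corners as (z,y,x)
  long long nid[4];
  double val[4];

  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        // quick reject: all 8 corners same side
        bool anyIn = false, anyOut = false;
        for (int dx = 0; dx <= 1 && !(anyIn && anyOut); ++dx)
          for (int dy = 0; dy <= 1; ++dy)
            for (int dz = 0; dz <= 1; ++dz) {
              double v = f[lin(z + dz, y + dy, x + dx)];
              if (v > level) anyIn = true; else anyOut = true;
            }
        if (!(anyIn && anyOut)) continue;

        for (int p = 0; p < 6; ++p) {
          int cur[3] = {z, y, x};
          for (int c = 0; c < 4; ++c) {
            corner[c][0] = cur[0]; corner[c][1] = cur[1]; corner[c][2] = cur[2];
            nid[c] = lin(cur[0], cur[1], cur[2]);
            val[c] = f[nid[c]];
            if (c < 3) cur[perms[p][c]] += 1;
          }
          bool in[4];
          int nin = 0;
          for (int c = 0; c < 4; ++c) { in[c] = val[c] > level; nin += in[c]; }
          if (nin == 0 || nin == 4) continue;

          int A[4], B[4], na = 0, nb = 0;  // inside / outside corner slots
          for (int c = 0; c < 4; ++c) { if (in[c]) A[na++] = c; else B[nb++] = c; }

          auto emit = [&](int i0, int i1, int i2) {
            // orient: normal should point from inside toward outside
            double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0};
            for (int c = 0; c < na; ++c)
              for (int d = 0; d < 3; ++d) cin[d] += corner[A[c]][d] / (double)na;
            for (int c = 0; c < nb; ++c)
              for (int d = 0; d < 3; ++d) cout[d] += corner[B[c]][d] / (double)nb;
            double p0[3] = {vz[i0], vy[i0], vx[i0]};
            double p1[3] = {vz[i1], vy[i1], vx[i1]};
            double p2[3] = {vz[i2], vy[i2], vx[i2]};
            double u[3] = {p1[0]-p0[0], p1[1]-p0[1], p1[2]-p0[2]};
            double w[3] = {p2[0]-p0[0], p2[1]-p0[1], p2[2]-p0[2]};
            double nrm[3] = {u[1]*w[2]-u[2]*w[1], u[2]*w[0]-u[0]*w[2], u[0]*w[1]-u[1]*w[0]};
            double dir[3] = {cout[0]-cin[0], cout[1]-cin[1], cout[2]-cin[2]};
            double d = nrm[0]*dir[0] + nrm[1]*dir[1] + nrm[2]*dir[2];
            if (d < 0) std::swap(i1, i2);
            f0.push_back(i0); f1.push_back(i1); f2.push_back(i2);
          };

          if (nin == 1) {
            int a = A[0];
            int e0 = vertex_on(nid[a], nid[B[0]], corner[a], corner[B[0]]);
            int e1 = vertex_on(nid[a], nid[B[1]], corner[a], corner[B[1]]);
            int e2 = vertex_on(nid[a], nid[B[2]], corner[a], corner[B[2]]);
            emit(e0, e1, e2);
          } else if (nin == 3) {
            int b = B[0];
            int e0 = vertex_on(nid[A[0]], nid[b], corner[A[0]], corner[b]);
            int e1 = vertex_on(nid[A[1]], nid[b], corner[A[1]], corner[b]);
            int e2 = vertex_on(nid[A[2]], nid[b], corner[A[2]], corner[b]);
            emit(e0, e1, e2);
          } else {  // nin == 2: quad split into two triangles
            int a0 = A[0], a1 = A[1], b0 = B[0], b1 = B[1];
            int e00 = vertex_on(nid[a0], nid[b0], corner[a0], corner[b0]);
            int e01 = vertex_on(nid[a0], nid[b1], corner[a0], corner[b1]);
            int e10 = vertex_on(nid[a1], nid[b0], corner[a1], corner[b0]);
            int e11 = vertex_on(nid[a1], nid[b1], corner[a1], corner[b1]);
            emit(e00, e01, e11);
            emit(e00, e11, e10);
          }
        }
      }

  int nv = (int)vz.size(), nf = (int)f0.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = vz[i]; V(i, 1) = vy[i]; V(i, 2) = vx[i]; }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) { F(i, 0) = f0[i] + 1; F(i, 1) = f1[i] + 1; F(i, 2) = f2[i] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Taubin lambda/mu mesh smoothing: alternating positive and negative
// Laplacian steps remove voxel-staircase jaggies with little shrinkage.
// [[Rcpp::export(name = ".taubin_smooth")]]
NumericMatrix taubin_smooth(NumericMatrix vertices, IntegerMatrix faces,
                            double lambda, double mu, int iterations) {
  int nv = vertices.nrow(), nf = faces.nrow();
  std::vector<std::vector<int>> adj(nv);
  for (int r = 0; r < nf; ++r) {
    int a = faces(r, 0) - 1, b = faces(r, 1) - 1, c = faces(r, 2) - 1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int i = 0; i < nv; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
  }
  std::vector<double> X(nv), Y(nv), Z(nv), dX(nv), dY(nv), dZ(nv);
  for (int i = 0; i < nv; ++i) {
    X[i] = vertices(i, 0); Y[i] = vertices(i, 1); Z[i] = vertices(i, 2);
  }
  for (int it = 0; it < iterations; ++it) {
    for (int pass = 0; pass < 2; ++pass) {
      double f = pass == 0 ? lambda : mu;
      for (int i = 0; i < nv; ++i) {
        if (adj[i].empty()) { dX[i] = dY[i] = dZ[i] = 0; continue; }
        double mx = 0, my = 0, mz = 0;
        for (int j : adj[i]) { mx += X[j]; my += Y[j]; mz += Z[j]; }
        double k = 1.0 / adj[i].size();
        dX[i] = mx * k - X[i]; dY[i] = my * k - Y[i]; dZ[i] = mz * k - Z[i];
      }
      for (int i = 0; i < nv; ++i) {
        X[i] += f * dX[i]; Y[i] += f * dY[i]; Z[i] += f * dZ[i];
      }
    }
  }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; ++i) { out(i, 0) = X[i]; out(i, 1) = Y[i]; out(i, 2) = Z[i]; }
  return out;
}
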