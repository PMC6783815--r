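#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Arrays are R 3D arrays, dim = c(nz, ny, nx), first index fastest.
// linear index = z + nz*(y + ny*x)

static void conn_offsets(int connectivity, std::vector<std::array<int,3>>& off) {
  off.clear();
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dz, dy, dx});
      }
}

// [[Rcpp::export(name = ".label_components3d")]]
IntegerVector label_components3d(LogicalVector vol, int connectivity) {
  IntegerVector dim = vol.attr("dim");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<std::array<int,3>> off;
  conn_offsets(connectivity, off);
  IntegerVector lab(vol.size(), 0);
  lab.attr("dim") = dim;
  int cur = 0;
  std::queue<int> q;
  for (R_xlen_t s = 0; s < vol.size(); ++s) {
    if (!vol[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    q.push((int)s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      int z = v % nz, rest = v / nz, y = rest % ny, x = rest / ny;
      for (auto& o : off) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int w = zz + nz * (yy + ny * xx);
        if (vol[w] && !lab[w]) { lab[w] = cur; q.push(w); }
      }
    }
  }
  return lab;
}

static LogicalVector morph_pass(const LogicalVector& vol, int connectivity,
                                bool dilate) {
  IntegerVector dim = vol.attr("dim");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<std::array<int,3>> off;
  conn_offsets(connectivity, off);
  LogicalVector out(vol.size());
  out.attr("dim") = dim;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int s = z + nz * (y + ny * x);
        bool val = vol[s];
        if (dilate ? val : !val) { out[s] = val; continue; }
        bool hit = false;
        for (auto& o : off) {
          int zz = z + o[0], yy = y + o[1], xx = x + o[2];
          bool nb;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            nb = false;  // outside the grid is background
          else
            nb = vol[zz + nz * (yy + ny * xx)];
          if (dilate ? nb : !nb) { hit = true; break; }
        }
        out[s] = dilate ? (val || hit) : (val && !hit);
      }
  return out;
}

// [[Rcpp::export(name = ".dilate3d")]]
LogicalVector dilate3d(LogicalVector vol, int connectivity, int iterations) {
  LogicalVector cur = vol;
  for (int i = 0; i < iterations; ++i) cur = morph_pass(cur, connectivity, true);
  if (iterations == 0) { cur = clone(vol); }
  return cur;
}

// [[Rcpp::export(name = ".erode3d")]]
LogicalVector erode3d(LogicalVector vol, int connectivity, int iterations) {
  LogicalVector cur = vol;
  for (int i = 0; i < iterations; ++i) cur = morph_pass(cur, connectivity, false);
  if (iterations == 0) { cur = clone(vol); }
  return cur;
}
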