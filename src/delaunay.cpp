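#include <Rcpp.h>
#include <map>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

// Incremental Bowyer-Watson 3D Delaunay tetrahedralization.
// Points are expected to be in general position (callers perturb
// degenerate inputs); marginal simplices are re-validated downstream
// against the empty-circumsphere invariant on the unperturbed
// coordinates, so floating-point predicate slack here is benign.

namespace {

struct Tet {
  int v[4];
  double cx, cy, cz, r2; // circumsphere
  bool alive;
};

// circumsphere of 4 points; returns false when (near-)degenerate
bool circumsphere(const std::vector<std::array<double,3> > &p,
                  int a, int b, int c, int d,
                  double &cx, double &cy, double &cz, double &r2) {
  double ax = p[a][0], ay = p[a][1], az = p[a][2];
  double m[3][3], rhs[3];
  int idx[3] = {b, c, d};
  for (int i = 0; i < 3; ++i) {
    double dx = p[idx[i]][0] - ax, dy = p[idx[i]][1] - ay, dz = p[idx[i]][2] - az;
    m[i][0] = 2.0 * dx; m[i][1] = 2.0 * dy; m[i][2] = 2.0 * dz;
    rhs[i] = dx * dx + dy * dy + dz * dz
      + 2.0 * (dx * ax + dy * ay + dz * az);
  }
  double det =
      m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1])
    - m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0])
    + m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
  if (std::abs(det) < 1e-12) return false;
  double x =
      (rhs[0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1])
     - m[0][1] * (rhs[1] * m[2][2] - m[1][2] * rhs[2])
     + m[0][2] * (rhs[1] * m[2][1] - m[1][1] * rhs[2])) / det;
  double y =
      (m[0][0] * (rhs[1] * m[2][2] - m[1][2] * rhs[2])
     - rhs[0] * (m[1][0] * m[2][2] - m[1][2] * m[2][0])
     + m[0][2] * (m[1][0] * rhs[2] - rhs[1] * m[2][0])) / det;
  double z =
      (m[0][0] * (m[1][1] * rhs[2] - rhs[1] * m[2][1])
     - m[0][1] * (m[1][0] * rhs[2] - rhs[1] * m[2][0])
     + rhs[0] * (m[1][0] * m[2][1] - m[1][1] * m[2][0])) / det;
  cx = x; cy = y; cz = z;
  double dx = ax - x, dy = ay - y, dz = az - z;
  r2 = dx * dx + dy * dy + dz * dz;
  return true;
}

typedef std::array<int,3> Face;

Face make_face(int a, int b, int c) {
  Face f = {a, b, c};
  std::sort(f.begin(), f.end());
  return f;
}

} // namespace

// [[Rcpp::export(name = ".delaunay_tets")]]
IntegerMatrix delaunay_tets(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a tetrahedralization");
  std::vector<std::array<double,3> > p(n + 4);
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) {
    p[i][0] = pts(i, 0); p[i][1] = pts(i, 1); p[i][2] = pts(i, 2);
    cx += p[i][0]; cy += p[i][1]; cz += p[i][2];
  }
  cx /= n; cy /= n; cz /= n;
  double rad = 1.0;
  for (int i = 0; i < n; ++i) {
    double dx = p[i][0] - cx, dy = p[i][1] - cy, dz = p[i][2] - cz;
    rad = std::max(rad, std::sqrt(dx * dx + dy * dy + dz * dz));
  }
  double K = 120.0 * rad;
  // enclosing super-tetrahedron
  p[n]     = {cx - K, cy - K, cz - K};
  p[n + 1] = {cx + 3.0 * K, cy - K, cz - K};
  p[n + 2] = {cx, cy + 3.0 * K, cz - K};
  p[n + 3] = {cx, cy, cz + 3.0 * K};

  std::vector<Tet> tets;
  {
    Tet t; t.v[0] = n; t.v[1] = n + 1; t.v[2] = n + 2; t.v[3] = n + 3;
    if (!circumsphere(p, n, n + 1, n + 2, n + 3, t.cx, t.cy, t.cz, t.r2))
      stop("degenerate super-tetrahedron");
    t.alive = true;
    tets.push_back(t);
  }

  std::vector<int> bad;
  for (int ip = 0; ip < n; ++ip) {
    double px = p[ip][0], py = p[ip][1], pz = p[ip][2];
    bad.clear();
    for (size_t it = 0; it < tets.size(); ++it) {
      if (!tets[it].alive) continue;
      double dx = px - tets[it].cx, dy = py - tets[it].cy, dz = pz - tets[it].cz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < tets[it].r2 * (1.0 + 1e-10)) bad.push_back((int)it);
    }
    // boundary faces of the cavity = faces seen exactly once
    std::map<Face,int> fc;
    for (size_t k = 0; k < bad.size(); ++k) {
      const int *v = tets[bad[k]].v;
      fc[make_face(v[0], v[1], v[2])]++;
      fc[make_face(v[0], v[1], v[3])]++;
      fc[make_face(v[0], v[2], v[3])]++;
      fc[make_face(v[1], v[2], v[3])]++;
      tets[bad[k]].alive = false;
    }
    for (std::map<Face,int>::const_iterator it = fc.begin(); it != fc.end(); ++it) {
      if (it->second != 1) continue;
      Tet t;
      t.v[0] = it->first[0]; t.v[1] = it->first[1]; t.v[2] = it->first[2]; t.v[3] = ip;
      if (!circumsphere(p, t.v[0], t.v[1], t.v[2], t.v[3], t.cx, t.cy, t.cz, t.r2))
        continue; // degenerate sliver; drop
      t.alive = true;
      tets.push_back(t);
    }
  }

  std::vector<std::array<int,4> > out;
  for (size_t it = 0; it < tets.size(); ++it) {
    if (!tets[it].alive) continue;
    const int *v = tets[it].v;
    if (v[0] >= n || v[1] >= n || v[2] >= n || v[3] >= n) continue;
    std::array<int,4> o = {v[0] + 1, v[1] + 1, v[2] + 1, v[3] + 1};
    std::sort(o.begin(), o.end());
    out.push_back(o);
  }
  std::sort(out.begin(), out.end());
  IntegerMatrix res((int)out.size(), 4);
  for (size_t i = 0; i < out.size(); ++i)
    for (int j = 0; j < 4; ++j) res((int)i, j) = out[i][j];
  return res;
}
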