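#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Incremental 3D convex hull. Returns triangular facets with outward unit
// normals and offsets (n . x <= off for every hull point), the hull volume,
// and the vertex set. Inputs are expected to be "generic" point clouds
// (colour loci in the tetrahedron); exactly coplanar inputs are reported as
// degenerate rather than triangulated.

struct Face {
  int a, b, c;
  double nx, ny, nz, off; // unit outward normal, offset
  bool alive;
};

static inline double dot3(double x1, double y1, double z1,
                          double x2, double y2, double z2) {
  return x1 * x2 + y1 * y2 + z1 * z2;
}

// unit outward normal for triangle (a,b,c), oriented away from ref
static bool make_face(const std::vector<double> &X, const std::vector<double> &Y,
                      const std::vector<double> &Z, int a, int b, int c,
                      double rx, double ry, double rz, Face &f) {
  double ux = X[b] - X[a], uy = Y[b] - Y[a], uz = Z[b] - Z[a];
  double vx = X[c] - X[a], vy = Y[c] - Y[a], vz = Z[c] - Z[a];
  double nx = uy * vz - uz * vy;
  double ny = uz * vx - ux * vz;
  double nz = ux * vy - uy * vx;
  double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
  if (nn < 1e-300) return false;
  nx /= nn; ny /= nn; nz /= nn;
  double off = dot3(nx, ny, nz, X[a], Y[a], Z[a]);
  // flip so the interior reference point is on the negative side
  if (dot3(nx, ny, nz, rx, ry, rz) > off) {
    std::swap(b, c);
    nx = -nx; ny = -ny; nz = -nz;
    off = -off;
  }
  f.a = a; f.b = b; f.c = c;
  f.nx = nx; f.ny = ny; f.nz = nz; f.off = off;
  f.alive = true;
  return true;
}

// [[Rcpp::export]]
List chull3d_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  List degen = List::create(
      _["volume"] = 0.0, _["degenerate"] = true,
      _["vertices"] = IntegerVector(0),
      _["faces"] = IntegerMatrix(0, 3),
      _["normals"] = NumericMatrix(0, 3),
      _["offsets"] = NumericVector(0),
      _["center"] = NumericVector::create(NA_REAL, NA_REAL, NA_REAL));
  if (n < 4) return degen;

  std::vector<double> X(n), Y(n), Z(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2);
    scale = std::max(scale, std::fabs(X[i]));
    scale = std::max(scale, std::fabs(Y[i]));
    scale = std::max(scale, std::fabs(Z[i]));
  }
  const double eps = 1e-9 * std::max(1.0, scale);

  // initial simplex: extreme in x, farthest point, widest triangle, widest tet
  int i0 = 0;
  for (int i = 1; i < n; ++i)
    if (X[i] < X[i0] || (X[i] == X[i0] && (Y[i] < Y[i0] || (Y[i] == Y[i0] && Z[i] < Z[i0]))))
      i0 = i;
  int i1 = -1; double best = eps * eps;
  for (int i = 0; i < n; ++i) {
    double d = dot3(X[i] - X[i0], Y[i] - Y[i0], Z[i] - Z[i0],
                    X[i] - X[i0], Y[i] - Y[i0], Z[i] - Z[i0]);
    if (d > best) { best = d; i1 = i; }
  }
  if (i1 < 0) return degen;
  int i2 = -1; best = eps;
  double ex = X[i1] - X[i0], ey = Y[i1] - Y[i0], ez = Z[i1] - Z[i0];
  for (int i = 0; i < n; ++i) {
    double wx = X[i] - X[i0], wy = Y[i] - Y[i0], wz = Z[i] - Z[i0];
    double cx = ey * wz - ez * wy, cy = ez * wx - ex * wz, cz = ex * wy - ey * wx;
    double d = std::sqrt(cx * cx + cy * cy + cz * cz);
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) return degen;
  // plane normal of (i0,i1,i2)
  {
    double wx = X[i2] - X[i0], wy = Y[i2] - Y[i0], wz = Z[i2] - Z[i0];
    double nx = ey * wz - ez * wy, ny = ez * wx - ex * wz, nz = ex * wy - ey * wx;
    double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
    nx /= nn; ny /= nn; nz /= nn;
    int i3 = -1; best = eps;
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(dot3(nx, ny, nz, X[i] - X[i0], Y[i] - Y[i0], Z[i] - Z[i0]));
      if (d > best) { best = d; i3 = i; }
    }
    if (i3 < 0) return degen;
    // interior reference point
    double rx = (X[i0] + X[i1] + X[i2] + X[i3]) / 4.0;
    double ry = (Y[i0] + Y[i1] + Y[i2] + Y[i3]) / 4.0;
    double rz = (Z[i0] + Z[i1] + Z[i2] + Z[i3]) / 4.0;

    std::vector<Face> faces;
    faces.reserve(8 * (size_t)std::sqrt((double)n) + 64);
    Face f;
    int init[4] = {i0, i1, i2, i3};
    int tri[4][3] = {{0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3}};
    for (int t = 0; t < 4; ++t) {
      if (!make_face(X, Y, Z, init[tri[t][0]], init[tri[t][1]], init[tri[t][2]],
                     rx, ry, rz, f))
        return degen;
      faces.push_back(f);
    }

    std::vector<int> visible;
    std::vector<long long> edges; // directed edges of visible faces
    for (int p = 0; p < n; ++p) {
      if (p == i0 || p == i1 || p == i2 || p == i3) continue;
      visible.clear();
      for (size_t j = 0; j < faces.size(); ++j) {
        if (!faces[j].alive) continue;
        if (dot3(faces[j].nx, faces[j].ny, faces[j].nz, X[p], Y[p], Z[p]) >
            faces[j].off + eps)
          visible.push_back((int)j);
      }
      if (visible.empty()) continue;
      edges.clear();
      std::unordered_set<long long> eset;
      for (int vi : visible) {
        const Face &g = faces[vi];
        long long e1 = (long long)g.a * n + g.b;
        long long e2 = (long long)g.b * n + g.c;
        long long e3 = (long long)g.c * n + g.a;
        edges.push_back(e1); edges.push_back(e2); edges.push_back(e3);
        eset.insert(e1); eset.insert(e2); eset.insert(e3);
        faces[vi].alive = false;
      }
      for (long long e : edges) {
        int a = (int)(e / n), b = (int)(e % n);
        if (eset.count((long long)b * n + a)) continue; // interior edge
        if (make_face(X, Y, Z, a, b, p, rx, ry, rz, f)) faces.push_back(f);
      }
    }

    // collect alive faces, vertices, volume
    int m = 0;
    for (size_t j = 0; j < faces.size(); ++j) if (faces[j].alive) ++m;
    IntegerMatrix F(m, 3);
    NumericMatrix N(m, 3);
    NumericVector O(m);
    std::vector<bool> used(n, false);
    double vol = 0.0;
    int k = 0;
    for (size_t j = 0; j < faces.size(); ++j) {
      if (!faces[j].alive) continue;
      const Face &g = faces[j];
      F(k, 0) = g.a + 1; F(k, 1) = g.b + 1; F(k, 2) = g.c + 1;
      N(k, 0) = g.nx; N(k, 1) = g.ny; N(k, 2) = g.nz;
      O[k] = g.off;
      used[g.a] = used[g.b] = used[g.c] = true;
      double ax = X[g.a] - rx, ay = Y[g.a] - ry, az = Z[g.a] - rz;
      double bx = X[g.b] - rx, by = Y[g.b] - ry, bz = Z[g.b] - rz;
      double cx = X[g.c] - rx, cy = Y[g.c] - ry, cz = Z[g.c] - rz;
      vol += (ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
              az * (bx * cy - by * cx)) / 6.0;
      ++k;
    }
    std::vector<int> verts;
    for (int i = 0; i < n; ++i) if (used[i]) verts.push_back(i + 1);
    return List::create(
        _["volume"] = vol, _["degenerate"] = false,
        _["vertices"] = IntegerVector(verts.begin(), verts.end()),
        _["faces"] = F, _["normals"] = N, _["offsets"] = O,
        _["center"] = NumericVector::create(rx, ry, rz));
  }
}

// point-in-polytope with early exit: x inside iff n_j . x <= off_j + tol
// [[Rcpp::export]]
LogicalVector in_hull_cpp(NumericMatrix pts, NumericMatrix normals,
                          NumericVector offsets, double tol) {
  const int n = pts.nrow(), m = normals.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    bool inside = true;
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    for (int j = 0; j < m; ++j) {
      if (normals(j, 0) * x + normals(j, 1) * y + normals(j, 2) * z >
          offsets[j] + tol) {
        inside = false;
        break;
      }
    }
    out[i] = inside;
  }
  return out;
}
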