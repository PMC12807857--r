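// Isosurface area via marching tetrahedra on a scalar field, and convex
// hull volume via an incremental (quickhull-style) algorithm. Field arrays
// use dim = c(nz, ny, nx), z fastest.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t idx3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
}

struct V3 {
  double x, y, z;
};
static inline V3 vsub(const V3 &a, const V3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline V3 vcross(const V3 &a, const V3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
static inline double vdot(const V3 &a, const V3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline double vnorm(const V3 &a) { return std::sqrt(vdot(a, a)); }

static inline double tri_area(const V3 &a, const V3 &b, const V3 &c) {
  return 0.5 * vnorm(vcross(vsub(b, a), vsub(c, a)));
}

// Each cube is split into six tetrahedra sharing the main diagonal 0-7.
// Cube corner c in 0..7 sits at offset (bit0, bit1, bit2) = (dx, dy, dz).
static const int TETS[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                               {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

// Total area of the level-set surface {vol == level}, in physical units
// given per-axis spacing (z, y, x).
// [[Rcpp::export(name = ".cpp_isosurface_area")]]
double cpp_isosurface_area(NumericVector vol, IntegerVector dim,
                           double level, NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  double total = 0.0;
  double vals[8];
  V3 pos[8];
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        double vmin = 1e300, vmax = -1e300;
        for (int c = 0; c < 8; ++c) {
          int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
          double v = vol[idx3(z + dz, y + dy, x + dx, nz, ny)];
          vals[c] = v;
          if (v < vmin) vmin = v;
          if (v > vmax) vmax = v;
          pos[c] = {(x + dx) * sx, (y + dy) * sy, (z + dz) * sz};
        }
        if (vmax < level || vmin >= level) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tet = TETS[t];
          int inside[4], outside[4], ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            if (vals[tet[k]] >= level) inside[ni++] = tet[k];
            else outside[no++] = tet[k];
          }
          if (ni == 0 || ni == 4) continue;
          auto interp = [&](int i, int j) -> V3 {
            double t0 = (level - vals[i]) / (vals[j] - vals[i]);
            return {pos[i].x + t0 * (pos[j].x - pos[i].x),
                    pos[i].y + t0 * (pos[j].y - pos[i].y),
                    pos[i].z + t0 * (pos[j].z - pos[i].z)};
          };
          if (ni == 1) {
            V3 a = interp(inside[0], outside[0]);
            V3 b = interp(inside[0], outside[1]);
            V3 c = interp(inside[0], outside[2]);
            total += tri_area(a, b, c);
          } else if (ni == 3) {
            V3 a = interp(inside[0], outside[0]);
            V3 b = interp(inside[1], outside[0]);
            V3 c = interp(inside[2], outside[0]);
            total += tri_area(a, b, c);
          } else {  // ni == 2: quad split into two triangles
            V3 a = interp(inside[0], outside[0]);
            V3 b = interp(inside[0], outside[1]);
            V3 c = interp(inside[1], outside[0]);
            V3 d = interp(inside[1], outside[1]);
            total += tri_area(a, b, c) + tri_area(b, c, d);
          }
        }
      }
  return total;
}

// ---------------------------------------------------------------------------
// Convex hull volume (incremental construction with full visibility scan).

struct Face {
  int a, b, c;       // vertex indices, outward orientation
  V3 n;              // outward normal (not normalized)
  double d;          // plane offset: n . p = d on the face
  bool alive;
};

static Face make_face(int a, int b, int c, const std::vector<V3> &P,
                      const V3 &interior) {
  Face f;
  f.a = a; f.b = b; f.c = c;
  f.n = vcross(vsub(P[b], P[a]), vsub(P[c], P[a]));
  f.d = vdot(f.n, P[a]);
  if (vdot(f.n, interior) > f.d) {  // flip to make the normal outward
    std::swap(f.b, f.c);
    f.n = {-f.n.x, -f.n.y, -f.n.z};
    f.d = -f.d;
  }
  f.alive = true;
  return f;
}

// [[Rcpp::export(name = ".cpp_convex_hull_volume")]]
double cpp_convex_hull_volume(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) return 0.0;
  std::vector<V3> P(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
  }
  for (int i = 1; i < n; ++i) scale = std::max(scale, vnorm(vsub(P[i], P[0])));
  if (scale == 0.0) return 0.0;
  double eps = 1e-9 * scale;

  // initial simplex: two extreme points, farthest from line, farthest from plane
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (P[i].x < P[i0].x) i0 = i;
    if (P[i].x > P[i1].x) i1 = i;
  }
  if (i0 == i1) { for (int i = 0; i < n; ++i) { if (P[i].y < P[i0].y) i0 = i; if (P[i].y > P[i1].y) i1 = i; } }
  if (i0 == i1) return 0.0;
  int i2 = -1; double best = eps;
  V3 dir = vsub(P[i1], P[i0]);
  for (int i = 0; i < n; ++i) {
    V3 w = vsub(P[i], P[i0]);
    double dist = vnorm(vcross(w, dir)) / vnorm(dir);
    if (dist > best) { best = dist; i2 = i; }
  }
  if (i2 < 0) return 0.0;  // collinear
  int i3 = -1; best = eps;
  V3 nrm = vcross(vsub(P[i1], P[i0]), vsub(P[i2], P[i0]));
  double nn = vnorm(nrm);
  for (int i = 0; i < n; ++i) {
    double dist = std::fabs(vdot(nrm, vsub(P[i], P[i0]))) / nn;
    if (dist > best) { best = dist; i3 = i; }
  }
  if (i3 < 0) return 0.0;  // coplanar

  V3 interior = {(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
                 (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
                 (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};
  std::vector<Face> faces;
  faces.push_back(make_face(i0, i1, i2, P, interior));
  faces.push_back(make_face(i0, i1, i3, P, interior));
  faces.push_back(make_face(i0, i2, i3, P, interior));
  faces.push_back(make_face(i1, i2, i3, P, interior));

  std::vector<char> done(n, 0);
  done[i0] = done[i1] = done[i2] = done[i3] = 1;
  bool changed = true;
  while (changed) {
    changed = false;
    // farthest outside point over all alive faces
    int bestPt = -1; double bestDist = eps;
    for (int i = 0; i < n; ++i) {
      if (done[i]) continue;
      for (size_t f = 0; f < faces.size(); ++f) {
        if (!faces[f].alive) continue;
        double dist = vdot(faces[f].n, P[i]) - faces[f].d;
        double nl = vnorm(faces[f].n);
        if (nl > 0 && dist / nl > bestDist) { bestDist = dist / nl; bestPt = i; }
      }
    }
    if (bestPt < 0) break;
    int p = bestPt;
    done[p] = 1;
    // visible faces and horizon edges
    std::vector<std::pair<int, int>> edges;
    for (size_t f = 0; f < faces.size(); ++f) {
      Face &fc = faces[f];
      if (!fc.alive) continue;
      double nl = vnorm(fc.n);
      if (vdot(fc.n, P[p]) - fc.d > eps * nl) {
        fc.alive = false;
        int e[3][2] = {{fc.a, fc.b}, {fc.b, fc.c}, {fc.c, fc.a}};
        for (int k = 0; k < 3; ++k) {
          int u = e[k][0], v = e[k][1];
          bool found = false;
          for (size_t j = 0; j < edges.size(); ++j) {
            if ((edges[j].first == v && edges[j].second == u) ||
                (edges[j].first == u && edges[j].second == v)) {
              edges.erase(edges.begin() + j);
              found = true;
              break;
            }
          }
          if (!found) edges.push_back({u, v});
        }
      }
    }
    for (auto &e : edges)
      faces.push_back(make_face(e.first, e.second, p, P, interior));
    changed = true;
  }

  double vol = 0.0;
  for (auto &f : faces) {
    if (!f.alive) continue;
    V3 a = vsub(P[f.a], interior), b = vsub(P[f.b], interior),
       c = vsub(P[f.c], interior);
    vol += std::fabs(vdot(a, vcross(b, c))) / 6.0;
  }
  return vol;
}

// Membership test against the convex hull of `pts`: for each row of
// `query`, TRUE iff the point lies inside (or within `tol` of) the hull.
// Rebuilds the hull and tests against its face planes.
// [[Rcpp::export(name = ".cpp_in_convex_hull")]]
LogicalVector cpp_in_convex_hull(NumericMatrix pts, NumericMatrix query,
                                 double tol) {
  int n = pts.nrow(), m = query.nrow();
  LogicalVector out(m, false);
  if (n < 4) return out;
  // run the incremental construction (duplicated bookkeeping kept local)
  std::vector<V3> P(n);
  for (int i = 0; i < n; ++i) P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
  double scale = 0.0;
  for (int i = 1; i < n; ++i) scale = std::max(scale, vnorm(vsub(P[i], P[0])));
  if (scale == 0.0) return out;
  double eps = 1e-9 * scale;
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (P[i].x < P[i0].x) i0 = i;
    if (P[i].x > P[i1].x) i1 = i;
  }
  if (i0 == i1) { for (int i = 0; i < n; ++i) { if (P[i].y < P[i0].y) i0 = i; if (P[i].y > P[i1].y) i1 = i; } }
  if (i0 == i1) return out;
  int i2 = -1; double best = eps;
  V3 dir = vsub(P[i1], P[i0]);
  for (int i = 0; i < n; ++i) {
    V3 w = vsub(P[i], P[i0]);
    double dist = vnorm(vcross(w, dir)) / vnorm(dir);
    if (dist > best) { best = dist; i2 = i; }
  }
  if (i2 < 0) return out;
  int i3 = -1; best = eps;
  V3 nrm = vcross(vsub(P[i1], P[i0]), vsub(P[i2], P[i0]));
  double nn = vnorm(nrm);
  for (int i = 0; i < n; ++i) {
    double dist = std::fabs(vdot(nrm, vsub(P[i], P[i0]))) / nn;
    if (dist > best) { best = dist; i3 = i; }
  }
  if (i3 < 0) return out;
  V3 interior = {(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
                 (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
                 (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};
  std::vector<Face> faces;
  faces.push_back(make_face(i0, i1, i2, P, interior));
  faces.push_back(make_face(i0, i1, i3, P, interior));
  faces.push_back(make_face(i0, i2, i3, P, interior));
  faces.push_back(make_face(i1, i2, i3, P, interior));
  std::vector<char> done(n, 0);
  done[i0] = done[i1] = done[i2] = done[i3] = 1;
  bool changed = true;
  while (changed) {
    changed = false;
    int bestPt = -1; double bestDist = eps;
    for (int i = 0; i < n; ++i) {
      if (done[i]) continue;
      for (size_t f = 0; f < faces.size(); ++f) {
        if (!faces[f].alive) continue;
        double dist = vdot(faces[f].n, P[i]) - faces[f].d;
        double nl = vnorm(faces[f].n);
        if (nl > 0 && dist / nl > bestDist) { bestDist = dist / nl; bestPt = i; }
      }
    }
    if (bestPt < 0) break;
    int p = bestPt;
    done[p] = 1;
    std::vector<std::pair<int, int>> edges;
    for (size_t f = 0; f < faces.size(); ++f) {
      Face &fc = faces[f];
      if (!fc.alive) continue;
      double nl = vnorm(fc.n);
      if (vdot(fc.n, P[p]) - fc.d > eps * nl) {
        fc.alive = false;
        int e[3][2] = {{fc.a, fc.b}, {fc.b, fc.c}, {fc.c, fc.a}};
        for (int k = 0; k < 3; ++k) {
          int u = e[k][0], v = e[k][1];
          bool found = false;
          for (size_t j = 0; j < edges.size(); ++j) {
            if ((edges[j].first == v && edges[j].second == u) ||
                (edges[j].first == u && edges[j].second == v)) {
              edges.erase(edges.begin() + j);
              found = true;
              break;
            }
          }
          if (!found) edges.push_back({u, v});
        }
      }
    }
    for (auto &e : edges)
      faces.push_back(make_face(e.first, e.second, p, P, interior));
    changed = true;
  }
  for (int q = 0; q < m; ++q) {
    V3 pt = {query(q, 0), query(q, 1), query(q, 2)};
    bool inside = true;
    for (auto &f : faces) {
      if (!f.alive) continue;
      double nl = vnorm(f.n);
      if (nl > 0 && vdot(f.n, pt) - f.d > tol * nl) { inside = false; break; }
    }
    out[q] = inside;
  }
  return out;
}
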