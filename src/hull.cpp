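#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Restricted gift-wrapping (Jarvis march) on a 2D point set.
//
// The walk starts at the lowest point and repeatedly moves to the candidate
// within physical distance td that makes the sharpest available outward turn
// (the classical Jarvis selection restricted to the td-disc). Where the
// convex-hull jump would exceed td the most extreme reachable point lies on
// the object boundary, so the walk follows the boundary into the concavity;
// concavities whose mouth is narrower than td are bridged.

struct Cand { double ang; double d2; int idx; };

static inline double cross3(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

// Proper segment intersection test (shared endpoints allowed).
static bool seg_intersect(double ax, double ay, double bx, double by,
                          double cx, double cy, double dx, double dy) {
  double d1 = cross3(cx, cy, dx, dy, ax, ay);
  double d2 = cross3(cx, cy, dx, dy, bx, by);
  double d3 = cross3(ax, ay, bx, by, cx, cy);
  double d4 = cross3(ax, ay, bx, by, dx, dy);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
    return true;
  return false;
}

// Clockwise angle from vector v to vector w, in (0, 2*pi].
static inline double cw_angle(double vx, double vy, double wx, double wy) {
  double a = std::atan2(vy, vx) - std::atan2(wy, wx);
  while (a <= 0) a += 2.0 * M_PI;
  while (a > 2.0 * M_PI) a -= 2.0 * M_PI;
  return a;
}

// Returns 1-based indices of the walk polygon (counter-clockwise order), or
// an empty vector when the walk fails to close (caller keeps the input).
// td <= 0 or non-finite means unrestricted (plain convex hull).
// [[Rcpp::export]]
IntegerVector cpp_hull_walk(NumericMatrix pts, double td) {
  int n = pts.nrow();
  if (n <= 2) {
    IntegerVector all(n);
    for (int i = 0; i < n; ++i) all[i] = i + 1;
    return all;
  }
  bool restricted = R_finite(td) && td > 0;
  double td2 = restricted ? td * td : 0.0;

  int start = 0;
  for (int i = 1; i < n; ++i) {
    if (pts(i, 1) < pts(start, 1) ||
        (pts(i, 1) == pts(start, 1) && pts(i, 0) < pts(start, 0)))
      start = i;
  }

  std::vector<int> poly;
  poly.push_back(start);
  int cur = start;
  // Incoming direction at the start: along -x, so that -v = +x and the first
  // pick is the smallest-polar-angle point, as in the classical march.
  double vx = -1.0, vy = 0.0;
  int maxsteps = 8 * n + 64;
  std::vector<Cand> cand;
  cand.reserve(n);

  for (int step = 0; step < maxsteps; ++step) {
    double px = pts(cur, 0), py = pts(cur, 1);
    cand.clear();
    for (int i = 0; i < n; ++i) {
      if (i == cur) continue;
      double ddx = pts(i, 0) - px, ddy = pts(i, 1) - py;
      double d2 = ddx * ddx + ddy * ddy;
      if (d2 == 0) continue;
      if (restricted && d2 > td2) continue;
      double a = cw_angle(-vx, -vy, ddx, ddy);
      // After the first step a full wrap (a == 2*pi) is an exact backtrack
      // along the incoming edge: rank it last so collinear chains do not
      // close the polygon prematurely.
      if (step > 0 && a > 2.0 * M_PI - 1e-12) a = 0.0;
      cand.push_back({a, d2, i});
    }
    if (cand.empty()) return IntegerVector(0);
    // Largest clockwise turn first; nearest first among collinear candidates.
    std::sort(cand.begin(), cand.end(), [](const Cand& a, const Cand& b) {
      if (a.ang != b.ang) return a.ang > b.ang;
      return a.d2 < b.d2;
    });
    int nxt = -1;
    int prev = poly.size() >= 2 ? poly[poly.size() - 2] : -1;
    for (size_t k = 0; k < cand.size(); ++k) {
      int i = cand[k].idx;
      if (i == prev && cand.size() > 1) continue;  // avoid immediate U-turn
      // reject edges crossing the existing chain
      bool bad = false;
      for (size_t e = 0; e + 2 < poly.size(); ++e) {
        if (seg_intersect(px, py, pts(i, 0), pts(i, 1),
                          pts(poly[e], 0), pts(poly[e], 1),
                          pts(poly[e + 1], 0), pts(poly[e + 1], 1))) {
          bad = true; break;
        }
      }
      if (!bad) { nxt = i; break; }
    }
    if (nxt < 0) return IntegerVector(0);
    if (nxt == start && poly.size() >= 3) {
      IntegerVector out(poly.size());
      for (size_t i = 0; i < poly.size(); ++i) out[i] = poly[i] + 1;
      return out;
    }
    vx = pts(nxt, 0) - px;
    vy = pts(nxt, 1) - py;
    poly.push_back(nxt);
    cur = nxt;
  }
  return IntegerVector(0);  // did not close: caller falls back to identity
}

// Even-odd point-in-polygon test.
static bool pnpoly(const std::vector<double>& qx, const std::vector<double>& qy,
                   double x, double y) {
  bool in = false;
  size_t nv = qx.size();
  for (size_t i = 0, j = nv - 1; i < nv; j = i++) {
    if (((qy[i] > y) != (qy[j] > y)) &&
        (x < (qx[j] - qx[i]) * (y - qy[i]) / (qy[j] - qy[i]) + qx[i]))
      in = !in;
  }
  return in;
}

// 2D 8-connected labelling of a binary matrix (helper for the slice wrapper).
static void label2d(const std::vector<char>& m, int nx, int ny,
                    std::vector<int>& lab, int& nlab) {
  lab.assign((size_t)nx * ny, 0);
  nlab = 0;
  std::vector<int> stack;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int i = x + nx * y;
      if (!m[i] || lab[i]) continue;
      lab[i] = ++nlab;
      stack.clear(); stack.push_back(i);
      while (!stack.empty()) {
        int j = stack.back(); stack.pop_back();
        int jx = j % nx, jy = j / nx;
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b) {
            if (!a && !b) continue;
            int qx2 = jx + a, qy2 = jy + b;
            if (qx2 < 0 || qy2 < 0 || qx2 >= nx || qy2 >= ny) continue;
            int q = qx2 + nx * qy2;
            if (m[q] && !lab[q]) { lab[q] = nlab; stack.push_back(q); }
          }
      }
    }
}

// Restricted hull of one binary slice. Pixel (i, j) (0-based) has its centre
// at (i * sx, j * sy). Processed per 8-connected component; the output is the
// union of the rasterized walk polygons with the input (growth-only).
// [[Rcpp::export]]
LogicalMatrix cpp_restricted_hull_slice(LogicalMatrix slice, double sx,
                                        double sy, double td) {
  int nx = slice.nrow(), ny = slice.ncol();
  std::vector<char> m((size_t)nx * ny);
  int nfg = 0;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      m[x + nx * y] = slice(x, y) ? 1 : 0;
      nfg += m[x + nx * y];
    }
  LogicalMatrix out = clone(slice);
  if (nfg <= 2) return out;

  std::vector<int> lab; int nlab = 0;
  label2d(m, nx, ny, lab, nlab);

  for (int l = 1; l <= nlab; ++l) {
    // boundary pixels of this component (4-neighbour background or edge)
    std::vector<int> bx, by;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (lab[x + nx * y] != l) continue;
        bool b = (x == 0 || y == 0 || x == nx - 1 || y == ny - 1);
        if (!b) {
          b = !m[(x - 1) + nx * y] || !m[(x + 1) + nx * y] ||
              !m[x + nx * (y - 1)] || !m[x + nx * (y + 1)];
        }
        if (b) { bx.push_back(x); by.push_back(y); }
      }
    if (bx.size() <= 2) continue;
    NumericMatrix pts(bx.size(), 2);
    for (size_t i = 0; i < bx.size(); ++i) {
      pts(i, 0) = bx[i] * sx;
      pts(i, 1) = by[i] * sy;
    }
    IntegerVector poly = cpp_hull_walk(pts, td);
    if (poly.size() < 3) continue;
    std::vector<double> qx(poly.size()), qy(poly.size());
    double x0 = 1e300, x1 = -1e300, y0 = 1e300, y1 = -1e300;
    for (int i = 0; i < poly.size(); ++i) {
      qx[i] = pts(poly[i] - 1, 0);
      qy[i] = pts(poly[i] - 1, 1);
      x0 = std::min(x0, qx[i]); x1 = std::max(x1, qx[i]);
      y0 = std::min(y0, qy[i]); y1 = std::max(y1, qy[i]);
    }
    int ix0 = std::max(0, (int)std::floor(x0 / sx));
    int ix1 = std::min(nx - 1, (int)std::ceil(x1 / sx));
    int iy0 = std::max(0, (int)std::floor(y0 / sy));
    int iy1 = std::min(ny - 1, (int)std::ceil(y1 / sy));
    for (int y = iy0; y <= iy1; ++y)
      for (int x = ix0; x <= ix1; ++x) {
        if (out(x, y)) continue;
        if (pnpoly(qx, qy, x * sx, y * sy)) out(x, y) = true;
      }
  }
  return out;
}
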