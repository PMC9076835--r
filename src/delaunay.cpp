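#include <Rcpp.h>
#include <cmath>
#include <map>
#include <utility>
#include <vector>

using namespace Rcpp;

// Incremental Bowyer-Watson Delaunay triangulation.
//
// Coordinates are rescaled to the unit box internally so that all
// floating-point predicates run on O(1) numbers regardless of the input
// units (micrometres here). Points exactly on a circumcircle are treated
// as outside it, which keeps exactly cocircular configurations (e.g. the
// corners of a square) triangulated with one of the two valid diagonals.

struct Tri {
  int a, b, c;       // vertex indices, CCW
  double cx, cy, r2; // circumcircle
  bool alive;
};

static inline double orient2d(double ax, double ay, double bx, double by,
                              double px, double py) {
  return (bx - ax) * (py - ay) - (by - ay) * (px - ax);
}

static bool circumcircle(const std::vector<double> &px,
                         const std::vector<double> &py, int a, int b, int c,
                         double &cx, double &cy, double &r2) {
  const double ax = px[a], ay = py[a], bx = px[b], by = py[b], qx = px[c],
               qy = py[c];
  const double d = 2.0 * (ax * (by - qy) + bx * (qy - ay) + qx * (ay - by));
  if (std::fabs(d) < 1e-14)
    return false;
  const double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by,
               c2 = qx * qx + qy * qy;
  cx = (a2 * (by - qy) + b2 * (qy - ay) + c2 * (ay - by)) / d;
  cy = (a2 * (qx - bx) + b2 * (ax - qx) + c2 * (bx - ax)) / d;
  const double dx = ax - cx, dy = ay - cy;
  r2 = dx * dx + dy * dy;
  return true;
}

static void push_tri(std::vector<Tri> &tris, const std::vector<double> &px,
                     const std::vector<double> &py, int a, int b, int c) {
  // orient CCW
  if (orient2d(px[a], py[a], px[b], py[b], px[c], py[c]) < 0.0)
    std::swap(b, c);
  Tri t;
  t.a = a;
  t.b = b;
  t.c = c;
  t.alive = true;
  if (!circumcircle(px, py, a, b, c, t.cx, t.cy, t.r2)) {
    // degenerate (collinear) triangle: give it an empty circumcircle so it
    // is never selected as part of a cavity; it can only arise transiently
    t.cx = t.cy = 0.0;
    t.r2 = -1.0;
  }
  tris.push_back(t);
}

// [[Rcpp::export(name = ".delaunay_cpp")]]
IntegerMatrix delaunay_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3)
    stop("need at least 3 points");

  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, x[i]);
    xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]);
    ymax = std::max(ymax, y[i]);
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0.0)
    stop("all points coincide");

  // rescale to unit box; indices 0..n-1 real, n..n+2 super-triangle
  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) {
    px[i] = (x[i] - xmin) / span;
    py[i] = (y[i] - ymin) / span;
  }
  px[n] = -50.0;
  py[n] = -40.0;
  px[n + 1] = 51.0;
  py[n + 1] = -40.0;
  px[n + 2] = 0.5;
  py[n + 2] = 80.0;

  std::vector<Tri> tris;
  tris.reserve(4 * n);
  push_tri(tris, px, py, n, n + 1, n + 2);

  const double eps = 1e-12;
  std::vector<int> bad;
  bad.reserve(64);

  for (int p = 0; p < n; ++p) {
    const double qx = px[p], qy = py[p];
    bad.clear();
    int seed = -1;      // a bad triangle that geometrically contains p
    double best = 1e30; // fallback: most violated circumcircle
    int best_id = -1;
    for (int t = 0; t < (int)tris.size(); ++t) {
      if (!tris[t].alive)
        continue;
      const double dx = qx - tris[t].cx, dy = qy - tris[t].cy;
      const double d2 = dx * dx + dy * dy;
      if (d2 < tris[t].r2 - eps) {
        bad.push_back(t);
        const double gap = d2 - tris[t].r2;
        if (gap < best) {
          best = gap;
          best_id = t;
        }
        if (seed < 0) {
          const Tri &tr = tris[t];
          if (orient2d(px[tr.a], py[tr.a], px[tr.b], py[tr.b], qx, qy) >=
                  -eps &&
              orient2d(px[tr.b], py[tr.b], px[tr.c], py[tr.c], qx, qy) >=
                  -eps &&
              orient2d(px[tr.c], py[tr.c], px[tr.a], py[tr.a], qx, qy) >= -eps)
            seed = t;
        }
      }
    }
    if (bad.empty())
      continue; // duplicate of an existing point: skip
    if (seed < 0)
      seed = best_id;

    // keep only the cavity component connected to the seed (guards against
    // a disconnected "bad" set from near-cocircular round-off)
    std::map<std::pair<int, int>, std::vector<int>> edge_owner;
    for (int id : bad) {
      const Tri &t = tris[id];
      const int v[3] = {t.a, t.b, t.c};
      for (int e = 0; e < 3; ++e) {
        int u = v[e], w = v[(e + 1) % 3];
        if (u > w)
          std::swap(u, w);
        edge_owner[std::make_pair(u, w)].push_back(id);
      }
    }
    std::map<int, bool> in_cavity;
    for (int id : bad)
      in_cavity[id] = false;
    std::vector<int> stack;
    stack.push_back(seed);
    in_cavity[seed] = true;
    while (!stack.empty()) {
      const int id = stack.back();
      stack.pop_back();
      const Tri &t = tris[id];
      const int v[3] = {t.a, t.b, t.c};
      for (int e = 0; e < 3; ++e) {
        int u = v[e], w = v[(e + 1) % 3];
        if (u > w)
          std::swap(u, w);
        for (int nb : edge_owner[std::make_pair(u, w)]) {
          if (nb != id && !in_cavity[nb]) {
            in_cavity[nb] = true;
            stack.push_back(nb);
          }
        }
      }
    }

    // boundary edges of the cavity = edges used exactly once within it
    std::map<std::pair<int, int>, int> edge_count;
    std::map<std::pair<int, int>, std::pair<int, int>> edge_oriented;
    for (int id : bad) {
      if (!in_cavity[id])
        continue;
      const Tri &t = tris[id];
      const int v[3] = {t.a, t.b, t.c};
      for (int e = 0; e < 3; ++e) {
        const int u = v[e], w = v[(e + 1) % 3];
        int ku = u, kw = w;
        if (ku > kw)
          std::swap(ku, kw);
        edge_count[std::make_pair(ku, kw)] += 1;
        edge_oriented[std::make_pair(ku, kw)] = std::make_pair(u, w);
      }
    }
    for (int id : bad)
      if (in_cavity[id])
        tris[id].alive = false;
    for (std::map<std::pair<int, int>, int>::iterator it = edge_count.begin();
         it != edge_count.end(); ++it) {
      if (it->second != 1)
        continue;
      const std::pair<int, int> uw = edge_oriented[it->first];
      push_tri(tris, px, py, uw.first, uw.second, p);
    }
  }

  int m = 0;
  for (size_t t = 0; t < tris.size(); ++t)
    if (tris[t].alive && tris[t].a < n && tris[t].b < n && tris[t].c < n)
      ++m;
  IntegerMatrix out(m, 3);
  int k = 0;
  for (size_t t = 0; t < tris.size(); ++t) {
    const Tri &tr = tris[t];
    if (!(tr.alive && tr.a < n && tr.b < n && tr.c < n))
      continue;
    out(k, 0) = tr.a + 1;
    out(k, 1) = tr.b + 1;
    out(k, 2) = tr.c + 1;
    ++k;
  }
  return out;
}
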