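#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bowyer-Watson incremental Delaunay triangulation of a 2-D point set.
// Returns 1-based triangle connectivity, counter-clockwise oriented.
// Points must be pre-deduplicated; near-degenerate cocircular quadruples
// are resolved by the insertion order (callers jitter grid points).

struct Tri {
  int a, b, c;      // vertex indices (0-based)
  double cx, cy, r2; // circumcircle centre and squared radius
  bool alive;
};

static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

static void circumcircle(const std::vector<double>& px,
                         const std::vector<double>& py, Tri& t) {
  double ax = px[t.a], ay = py[t.a];
  double bx = px[t.b], by = py[t.b];
  double cx = px[t.c], cy = py[t.c];
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-300) { // degenerate: huge circle
    t.cx = t.cy = 0.0; t.r2 = 1e300; return;
  }
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  t.cx = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  t.cy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  double dx = ax - t.cx, dy = ay - t.cy;
  t.r2 = dx * dx + dy * dy;
}

// [[Rcpp::export(name = ".cpp_delaunay")]]
IntegerMatrix cpp_delaunay(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) stop("need at least 3 points");
  std::vector<double> px(n + 3), py(n + 3);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1);
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  double dmax = std::max(xmax - xmin, ymax - ymin);
  if (dmax <= 0) stop("all points coincide");
  double midx = 0.5 * (xmin + xmax), midy = 0.5 * (ymin + ymax);
  // super-triangle far outside the hull
  px[n] = midx - 20.0 * dmax; py[n] = midy - 10.0 * dmax;
  px[n + 1] = midx + 20.0 * dmax; py[n + 1] = midy - 10.0 * dmax;
  px[n + 2] = midx; py[n + 2] = midy + 20.0 * dmax;

  std::vector<Tri> tris;
  Tri t0; t0.a = n; t0.b = n + 1; t0.c = n + 2; t0.alive = true;
  circumcircle(px, py, t0);
  tris.push_back(t0);

  std::vector<std::pair<int,int> > cavity; // boundary edges of the cavity
  for (int ip = 0; ip < n; ++ip) {
    double x = px[ip], y = py[ip];
    cavity.clear();
    for (size_t it = 0; it < tris.size(); ++it) {
      Tri& t = tris[it];
      if (!t.alive) continue;
      double dx = x - t.cx, dy = y - t.cy;
      if (dx * dx + dy * dy <= t.r2 * (1.0 + 1e-12)) {
        t.alive = false;
        int e[3][2] = {{t.a, t.b}, {t.b, t.c}, {t.c, t.a}};
        for (int k = 0; k < 3; ++k) {
          bool shared = false;
          for (size_t j = 0; j < cavity.size(); ++j) {
            if (cavity[j].first == e[k][1] && cavity[j].second == e[k][0]) {
              cavity.erase(cavity.begin() + j); shared = true; break;
            }
          }
          if (!shared) cavity.push_back(std::make_pair(e[k][0], e[k][1]));
        }
      }
    }
    for (size_t j = 0; j < cavity.size(); ++j) {
      Tri t; t.a = cavity[j].first; t.b = cavity[j].second; t.c = ip;
      if (orient2d(px[t.a], py[t.a], px[t.b], py[t.b], x, y) < 0)
        std::swap(t.a, t.b);
      t.alive = true;
      circumcircle(px, py, t);
      tris.push_back(t);
    }
    // periodic compaction keeps the scan cost bounded
    if (tris.size() > 4u * (size_t)(ip + 4)) {
      std::vector<Tri> keep;
      keep.reserve(tris.size());
      for (size_t it = 0; it < tris.size(); ++it)
        if (tris[it].alive) keep.push_back(tris[it]);
      tris.swap(keep);
    }
  }

  int m = 0;
  for (size_t it = 0; it < tris.size(); ++it) {
    Tri& t = tris[it];
    if (t.alive && t.a < n && t.b < n && t.c < n) ++m;
  }
  IntegerMatrix out(m, 3);
  int r = 0;
  for (size_t it = 0; it < tris.size(); ++it) {
    Tri& t = tris[it];
    if (t.alive && t.a < n && t.b < n && t.c < n) {
      out(r, 0) = t.a + 1; out(r, 1) = t.b + 1; out(r, 2) = t.c + 1;
      ++r;
    }
  }
  return out;
}
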