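// Voronoi adjacency by direct half-plane clipping of each cell.
//
// For every focal point the cell is cut from a large bounding square by the
// perpendicular bisectors with the other points, visited in order of
// increasing distance; clipping stops as soon as the next candidate's
// bisector provably cannot intersect the current cell. Two points share a
// Voronoi edge iff the surviving cell retains a positive-length edge on their
// bisector, so degenerate (point-contact) adjacencies such as the diagonals
// of a square lattice are excluded. Cells of hull-boundary points are the
// unbounded ones; pairs of far-reaching cells get an exact bisector test
// because their shared ridge may start beyond any finite clipping box.
#include <Rcpp.h>
#include <algorithm>
#include <limits>
#include <cmath>
#include <set>
#include <vector>
using namespace Rcpp;

struct ClipPoly {
  std::vector<double> vx, vy;
  std::vector<int> attr; // attr[k]: neighbor index of edge v[k] -> v[k+1]; -1 = box
};

static void clip_halfplane(ClipPoly& poly, double mx, double my,
                           double dx, double dy, int nbr, double tol) {
  const size_t m = poly.vx.size();
  if (m == 0) return;
  std::vector<double> nx_, ny_;
  std::vector<int> na_;
  nx_.reserve(m + 2); ny_.reserve(m + 2); na_.reserve(m + 2);
  std::vector<double> f(m);
  for (size_t k = 0; k < m; ++k)
    f[k] = (poly.vx[k] - mx) * dx + (poly.vy[k] - my) * dy;
  for (size_t k = 0; k < m; ++k) {
    const size_t k1 = (k + 1) % m;
    const double fa = f[k], fb = f[k1];
    const bool ain = fa <= tol, bin = fb <= tol;
    if (ain) {
      nx_.push_back(poly.vx[k]); ny_.push_back(poly.vy[k]);
      na_.push_back(poly.attr[k]);
      if (!bin) { // exiting: cut point, then travel along the bisector
        const double t = fa / (fa - fb);
        nx_.push_back(poly.vx[k] + t * (poly.vx[k1] - poly.vx[k]));
        ny_.push_back(poly.vy[k] + t * (poly.vy[k1] - poly.vy[k]));
        na_.push_back(nbr);
      }
    } else if (bin) { // re-entering: remainder of the original edge
      const double t = fa / (fa - fb);
      nx_.push_back(poly.vx[k] + t * (poly.vx[k1] - poly.vx[k]));
      ny_.push_back(poly.vy[k] + t * (poly.vy[k1] - poly.vy[k]));
      na_.push_back(poly.attr[k]);
    }
  }
  poly.vx.swap(nx_); poly.vy.swap(ny_); poly.attr.swap(na_);
}

// Full convex-hull boundary cycle (monotone chain) KEEPING collinear
// boundary points, so consecutive boundary points are true Delaunay/Voronoi
// neighbors even along straight hull runs.
static std::vector<int> hull_cycle(const NumericVector& x,
                                   const NumericVector& y) {
  const int n = x.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });
  auto cross = [&](int o, int a, int b) {
    return (x[a] - x[o]) * (y[b] - y[o]) - (y[a] - y[o]) * (x[b] - x[o]);
  };
  // strictly convex turns drop points; cross == 0 (collinear) is kept
  std::vector<int> lower, upper;
  for (int k = 0; k < n; ++k) {
    const int p = idx[k];
    while (lower.size() >= 2 &&
           cross(lower[lower.size() - 2], lower.back(), p) < 0)
      lower.pop_back();
    lower.push_back(p);
  }
  for (int k = n - 1; k >= 0; --k) {
    const int p = idx[k];
    while (upper.size() >= 2 &&
           cross(upper[upper.size() - 2], upper.back(), p) < 0)
      upper.pop_back();
    upper.push_back(p);
  }
  lower.pop_back();
  upper.pop_back();
  lower.insert(lower.end(), upper.begin(), upper.end());
  return lower;
}

// [[Rcpp::export]]
List cpp_voronoi_neighbors(const NumericVector& x, const NumericVector& y) {
  const int n = x.size();
  if (n < 4) stop("at least 4 points are required");
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  const double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) stop("degenerate point set: all points coincide");
  // collinearity check (tessellation undefined)
  {
    bool collinear = true;
    const double ax = x[0], ay = y[0];
    double bx = 0, by = 0;
    int ref = -1;
    for (int i = 1; i < n && ref < 0; ++i) {
      bx = x[i] - ax; by = y[i] - ay;
      if (bx * bx + by * by > 1e-24 * span * span) ref = i;
    }
    for (int i = 1; i < n; ++i) {
      const double cx = x[i] - ax, cy = y[i] - ay;
      if (std::fabs(bx * cy - by * cx) > 1e-12 * span * span) {
        collinear = false;
        break;
      }
    }
    if (collinear) stop("degenerate input: points are collinear, Voronoi tessellation is undefined");
  }
  const double big = 8.0 * span + 1.0;
  const double cx0 = 0.5 * (xmin + xmax), cy0 = 0.5 * (ymin + ymax);
  const double tol = 1e-12 * std::max(1.0, span * span);
  const double min_edge = 1e-7 * std::max(1.0, span);

  std::set<long long> pairs;
  LogicalVector bounded(n);
  std::vector<int> ord(n);
  std::vector<double> d2(n);
  std::vector<double> reach2(n, 0.0); // squared reach of each final cell

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      d2[j] = dx * dx + dy * dy;
      ord[j] = j;
    }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return d2[a] < d2[b]; });
    ClipPoly poly;
    poly.vx = {cx0 - big, cx0 + big, cx0 + big, cx0 - big};
    poly.vy = {cy0 - big, cy0 - big, cy0 + big, cy0 + big};
    poly.attr = {-1, -1, -1, -1};
    double maxd2 = 0;
    for (size_t k = 0; k < poly.vx.size(); ++k) {
      const double dx = poly.vx[k] - x[i], dy = poly.vy[k] - y[i];
      maxd2 = std::max(maxd2, dx * dx + dy * dy);
    }
    for (int q = 0; q < n; ++q) {
      const int j = ord[q];
      if (j == i) continue;
      if (d2[j] > 4.0 * maxd2) break; // bisector cannot reach the cell
      clip_halfplane(poly, 0.5 * (x[i] + x[j]), 0.5 * (y[i] + y[j]),
                     x[j] - x[i], y[j] - y[i], j, tol);
      maxd2 = 0;
      for (size_t k = 0; k < poly.vx.size(); ++k) {
        const double dx = poly.vx[k] - x[i], dy = poly.vy[k] - y[i];
        maxd2 = std::max(maxd2, dx * dx + dy * dy);
      }
    }
    reach2[i] = maxd2;
    const size_t m = poly.vx.size();
    for (size_t k = 0; k < m; ++k) {
      const size_t k1 = (k + 1) % m;
      const double ex = poly.vx[k1] - poly.vx[k];
      const double ey = poly.vy[k1] - poly.vy[k];
      if (std::sqrt(ex * ex + ey * ey) <= min_edge) continue;
      if (poly.attr[k] < 0) continue;
      const int j = poly.attr[k];
      const long long a = std::min(i, j), b = std::max(i, j);
      pairs.insert(a * (long long)n + b);
    }
  }

  // A ridge between two far-reaching cells can start at a sliver triangle's
  // remote circumcenter, beyond the clipping box, and be missed above. Such
  // a ridge implies a giant empty circle, so both cells must reach far from
  // the pattern; pairs of far-reaching cells are therefore re-decided
  // exactly by a 1-D feasibility test along the pair's bisector:
  // c(t) = m + t*u is a ridge point iff it is closer to the pair than to
  // every other point, and each such condition is linear in t.
  {
    std::vector<int> hull = hull_cycle(x, y);
    for (int i = 0; i < n; ++i) bounded[i] = true;
    for (size_t k = 0; k < hull.size(); ++k) bounded[hull[k]] = false;
    std::vector<int> far;
    const double far2 = 4.0 * span * span;
    for (int i = 0; i < n; ++i)
      if (reach2[i] > far2) far.push_back(i);
    for (size_t a = 0; a < far.size(); ++a) {
      for (size_t b = a + 1; b < far.size(); ++b) {
        const int i = far[a], j = far[b];
        const double mx = 0.5 * (x[i] + x[j]), my = 0.5 * (y[i] + y[j]);
        double ux = -(y[j] - y[i]), uy = x[j] - x[i];
        const double un = std::sqrt(ux * ux + uy * uy);
        if (un <= 0) continue;
        ux /= un; uy /= un;
        double tlo = -std::numeric_limits<double>::infinity();
        double thi = std::numeric_limits<double>::infinity();
        bool empty = false;
        for (int k2 = 0; k2 < n && !empty; ++k2) {
          if (k2 == i || k2 == j) continue;
          const double kx = x[k2] - x[i], ky = y[k2] - y[i];
          const double bk = -2.0 * (ux * kx + uy * ky);
          const double ak = -2.0 * ((mx - x[i]) * kx + (my - y[i]) * ky) +
                            kx * kx + ky * ky;
          if (bk > 0) tlo = std::max(tlo, -ak / bk);
          else if (bk < 0) thi = std::min(thi, -ak / bk);
          else if (ak <= 0) empty = true;
        }
        if (!empty && thi - tlo > min_edge) {
          const long long lo = std::min(i, j), hi = std::max(i, j);
          pairs.insert(lo * (long long)n + hi);
        }
      }
    }
  }

  const size_t ne = pairs.size();
  IntegerVector ei(ne), ej(ne);
  size_t t = 0;
  for (long long code : pairs) {
    ei[t] = (int)(code / n) + 1;
    ej[t] = (int)(code % n) + 1;
    ++t;
  }
  return List::create(_["i"] = ei, _["j"] = ej, _["bounded"] = bounded);
}
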