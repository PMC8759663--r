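// Neighborhood density maps and connected-component labelling.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int wrapi(int i, int n) { i %= n; if (i < 0) i += n; return i; }
static inline double mindiff(double a, double b, double L) {
  double d = a - b;
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

// counts(i, j) = number of agents within Euclidean distance `radius` of the
// center (i + 0.5, j + 0.5) of pixel (i, j), periodic metric. radius = 0 is
// containing-pixel binning (so raw counts sum to the number of agents).
// [[Rcpp::export]]
IntegerMatrix cpp_density_map(const NumericVector& x, const NumericVector& y,
                              double radius, int grid_size, bool periodic) {
  if (radius < 0) stop("radius must be >= 0");
  const int n = grid_size;
  IntegerMatrix counts(n, n);
  const int na = x.size();
  if (radius == 0) {
    for (int k = 0; k < na; ++k) {
      counts(wrapi((int)std::floor(x[k]), n), wrapi((int)std::floor(y[k]), n))++;
    }
    return counts;
  }
  const double r2 = radius * radius;
  const int span = (int)std::ceil(radius) + 1;
  const double L = (double)n;
  for (int k = 0; k < na; ++k) {
    const int ci = (int)std::floor(x[k]);
    const int cj = (int)std::floor(y[k]);
    for (int dj = -span; dj <= span; ++dj) {
      for (int di = -span; di <= span; ++di) {
        const int i = ci + di, j = cj + dj;
        if (!periodic && (i < 0 || i >= n || j < 0 || j >= n)) continue;
        const double px = i + 0.5, py = j + 0.5;
        double dx, dy;
        if (periodic) { dx = mindiff(x[k], px, L); dy = mindiff(y[k], py, L); }
        else { dx = x[k] - px; dy = y[k] - py; }
        if (dx * dx + dy * dy <= r2)
          counts(wrapi(i, n), wrapi(j, n))++;
      }
    }
  }
  return counts;
}

// Label connected foreground components (mask != 0). 8- or 4-connectivity,
// optional periodic wrap. Labels are 1..K in scan order; background is 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, bool eight,
                                   bool periodic) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  const int n8i[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int n8j[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = eight ? 8 : 4;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      if (mask(i0, j0) == 0 || lab(i0, j0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(j0 * nr + i0);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int i = p % nr, j = p / nr;
        for (int q = 0; q < nn; ++q) {
          int ii = i + n8i[q], jj = j + n8j[q];
          if (periodic) { ii = wrapi(ii, nr); jj = wrapi(jj, nc); }
          else if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) != 0 && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back(jj * nr + ii);
          }
        }
      }
    }
  }
  return lab;
}
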