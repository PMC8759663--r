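// Low-level stepping kernels for the agent-based aggregation model.
// All kernels use R's RNG (via Rcpp) so set.seed() governs every draw;
// draws are made in fixed agent order for bit-reproducibility.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int wrapi(int i, int n) { i %= n; if (i < 0) i += n; return i; }
static inline double wrapd(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L || x < 0) x = 0.0; // guard against rounding at the seam
  return x;
}
// minimum-image signed separation on a periodic interval
static inline double mindiff(double a, double b, double L) {
  double d = a - b;
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

// One explicit FTCS step of the chemoattractant field on a periodic square
// grid: 5-point-stencil diffusion, multiplicative decay (1 - k*dt), then
// deposition of s*dt at each agent's containing pixel.
// [[Rcpp::export]]
NumericMatrix cpp_field_step(const NumericMatrix& field,
                             const NumericVector& x, const NumericVector& y,
                             double D, double decay_k, double s, double dt) {
  const int n = field.nrow();
  if (field.ncol() != n) stop("field must be square");
  NumericMatrix out(n, n);
  const double a = D * dt;
  const double dec = 1.0 - decay_k * dt;
  for (int j = 0; j < n; ++j) {
    const int jm = wrapi(j - 1, n), jp = wrapi(j + 1, n);
    for (int i = 0; i < n; ++i) {
      const int im = wrapi(i - 1, n), ip = wrapi(i + 1, n);
      const double lap = field(im, j) + field(ip, j) + field(i, jm) +
                         field(i, jp) - 4.0 * field(i, j);
      out(i, j) = (field(i, j) + a * lap) * dec;
    }
  }
  const int na = x.size();
  const double sd = s * dt;
  for (int k = 0; k < na; ++k) {
    const int i = wrapi((int)std::floor(x[k]), n);
    const int j = wrapi((int)std::floor(y[k]), n);
    out(i, j) += sd;
  }
  return out;
}

// Bilinear interpolation of a periodic pixel-centered field at off-lattice
// positions. Pixel (i, j) covers [i, i+1) x [j, j+1); its value is attached
// to the center (i + 0.5, j + 0.5).
static double interp_at(const NumericMatrix& f, double x, double y, int n) {
  const double u = x - 0.5, v = y - 0.5;
  const int i0 = (int)std::floor(u), j0 = (int)std::floor(v);
  const double fx = u - i0, fy = v - j0;
  const int i0w = wrapi(i0, n), i1w = wrapi(i0 + 1, n);
  const int j0w = wrapi(j0, n), j1w = wrapi(j0 + 1, n);
  return f(i0w, j0w) * (1 - fx) * (1 - fy) + f(i1w, j0w) * fx * (1 - fy) +
         f(i0w, j1w) * (1 - fx) * fy + f(i1w, j1w) * fx * fy;
}

// [[Rcpp::export]]
NumericVector cpp_interp_field(const NumericMatrix& field,
                               const NumericVector& x, const NumericVector& y) {
  const int n = field.nrow();
  const int na = x.size();
  NumericVector out(na);
  for (int k = 0; k < na; ++k) out[k] = interp_at(field, x[k], y[k], n);
  return out;
}

// Central-difference gradient on the grid, bilinearly interpolated.
// [[Rcpp::export]]
NumericMatrix cpp_interp_gradient(const NumericMatrix& field,
                                  const NumericVector& x, const NumericVector& y) {
  const int n = field.nrow();
  NumericMatrix gx(n, n), gy(n, n);
  for (int j = 0; j < n; ++j) {
    const int jm = wrapi(j - 1, n), jp = wrapi(j + 1, n);
    for (int i = 0; i < n; ++i) {
      const int im = wrapi(i - 1, n), ip = wrapi(i + 1, n);
      gx(i, j) = 0.5 * (field(ip, j) - field(im, j));
      gy(i, j) = 0.5 * (field(i, jp) - field(i, jm));
    }
  }
  const int na = x.size();
  NumericMatrix out(na, 2);
  for (int k = 0; k < na; ++k) {
    out(k, 0) = interp_at(gx, x[k], y[k], n);
    out(k, 1) = interp_at(gy, x[k], y[k], n);
  }
  return out;
}

// Motility-state transitions. States: 0 = MOTILE, 1 = IMMOTILE_FIXED,
// 2 = IMMOTILE_STOCHASTIC, 3 = BLIND. At most one transition per step.
// [[Rcpp::export]]
List cpp_motility_step(const IntegerVector& state, const NumericVector& clock,
                       const NumericVector& c_local, double c_star,
                       double t_refractory, double p_reactivate,
                       double t_blind, double dt) {
  const int n = state.size();
  IntegerVector st = clone(state);
  NumericVector ck = clone(clock);
  for (int k = 0; k < n; ++k) {
    switch (st[k]) {
    case 0: // MOTILE
      if (c_local[k] >= c_star) { st[k] = 1; ck[k] = t_refractory; }
      break;
    case 1: // IMMOTILE_FIXED: clock counts down the refractory interval
      ck[k] -= dt;
      if (ck[k] <= 1e-12) { st[k] = 2; ck[k] = 0.0; }
      break;
    case 2: // IMMOTILE_STOCHASTIC: geometric wait for reactivation
      if (R::unif_rand() < p_reactivate) { st[k] = 3; ck[k] = t_blind; }
      break;
    case 3: // BLIND: gradient-ignoring Brownian interval
      ck[k] -= dt;
      if (ck[k] <= 1e-12) { st[k] = 0; ck[k] = 0.0; }
      break;
    default:
      stop("invalid motility state %d", st[k]);
    }
  }
  return List::create(_["state"] = st, _["clock"] = ck);
}

// Euler-Maruyama position update plus finite-size soft repulsion.
// MOTILE agents: chemotactic drift (receptor law) + Brownian noise;
// BLIND agents: Brownian noise only; immotile agents never move (they act
// as anchored obstacles for the repulsion pass).
// [[Rcpp::export]]
List cpp_position_step(const NumericVector& x, const NumericVector& y,
                       const IntegerVector& state, const NumericMatrix& field,
                       double D_agent, double chi0, double c_half,
                       double dt, double L, double r_agent) {
  const int n = field.nrow();
  const int na = x.size();
  NumericVector nx = clone(x), ny = clone(y);
  const double sig = std::sqrt(2.0 * D_agent * dt);

  // precompute grid gradient once per step
  NumericMatrix gx(n, n), gy(n, n);
  if (chi0 != 0.0) {
    for (int j = 0; j < n; ++j) {
      const int jm = wrapi(j - 1, n), jp = wrapi(j + 1, n);
      for (int i = 0; i < n; ++i) {
        const int im = wrapi(i - 1, n), ip = wrapi(i + 1, n);
        gx(i, j) = 0.5 * (field(ip, j) - field(im, j));
        gy(i, j) = 0.5 * (field(i, jp) - field(i, jm));
      }
    }
  }

  for (int k = 0; k < na; ++k) {
    const int st = state[k];
    if (st == 1 || st == 2) continue; // immotile: no move, no draws
    double dx = 0.0, dy = 0.0;
    if (st == 0 && chi0 != 0.0) {
      const double c = interp_at(field, x[k], y[k], n);
      const double gxa = interp_at(gx, x[k], y[k], n);
      const double gya = interp_at(gy, x[k], y[k], n);
      const double sat = 1.0 + c / c_half;
      const double chi = chi0 / (sat * sat);
      dx += chi * gxa * dt;
      dy += chi * gya * dt;
    }
    if (sig > 0.0) {
      dx += sig * R::norm_rand();
      dy += sig * R::norm_rand();
    }
    nx[k] = wrapd(x[k] + dx, L);
    ny[k] = wrapd(y[k] + dy, L);
  }

  // Pairwise soft repulsion within r_agent via a cell list. Each overlapping
  // pair is separated along its axis; only motile/blind members are displaced.
  if (r_agent > 0.0) {
    // flat linked-list cell structure; cell size >= r_agent so only the
    // 3x3 neighborhood needs scanning
    const double cell = std::max(r_agent, L / 512.0);
    int nc = (int)std::floor(L / cell);
    if (nc < 1) nc = 1;
    const double csize = L / nc;
    std::vector<int> head((size_t)nc * nc, -1), nxt(na, -1);
    for (int k = 0; k < na; ++k) {
      int ci = (int)std::floor(nx[k] / csize); if (ci >= nc) ci = nc - 1;
      int cj = (int)std::floor(ny[k] / csize); if (cj >= nc) cj = nc - 1;
      const size_t b = (size_t)cj * nc + ci;
      nxt[k] = head[b];
      head[b] = k;
    }
    NumericVector px = clone(nx), py = clone(ny); // displace from a frozen copy
    const double r2 = r_agent * r_agent;
    for (int cj = 0; cj < nc; ++cj) {
      for (int ci = 0; ci < nc; ++ci) {
        for (int ka = head[(size_t)cj * nc + ci]; ka >= 0; ka = nxt[ka]) {
          for (int dj = -1; dj <= 1; ++dj) {
            for (int di = -1; di <= 1; ++di) {
              const int oi = wrapi(ci + di, nc), oj = wrapi(cj + dj, nc);
              for (int kb = head[(size_t)oj * nc + oi]; kb >= 0; kb = nxt[kb]) {
                if (ka >= kb) continue; // each unordered pair once
                const double ddx = mindiff(nx[ka], nx[kb], L);
                const double ddy = mindiff(ny[ka], ny[kb], L);
                const double d2 = ddx * ddx + ddy * ddy;
                if (d2 >= r2) continue;
                const double d = std::sqrt(d2);
                double ux, uy;
                if (d > 1e-12) { ux = ddx / d; uy = ddy / d; }
                else { ux = 1.0; uy = 0.0; } // coincident: arbitrary fixed axis
                const double push = 0.5 * (r_agent - d);
                const bool ma = (state[ka] == 0 || state[ka] == 3);
                const bool mb = (state[kb] == 0 || state[kb] == 3);
                if (ma && mb) {
                  px[ka] = wrapd(px[ka] + push * ux, L);
                  py[ka] = wrapd(py[ka] + push * uy, L);
                  px[kb] = wrapd(px[kb] - push * ux, L);
                  py[kb] = wrapd(py[kb] - push * uy, L);
                } else if (ma) {
                  px[ka] = wrapd(px[ka] + 2.0 * push * ux, L);
                  py[ka] = wrapd(py[ka] + 2.0 * push * uy, L);
                } else if (mb) {
                  px[kb] = wrapd(px[kb] - 2.0 * push * ux, L);
                  py[kb] = wrapd(py[kb] - 2.0 * push * uy, L);
                }
              }
            }
          }
        }
      }
    }
    nx = px; ny = py;
  }
  return List::create(_["x"] = nx, _["y"] = ny);
}
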