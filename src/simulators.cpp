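#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Fast per-call RNG (xoshiro256++ with a ziggurat normal sampler), seeded
// from R's stream so set.seed() controls everything while the hot loops
// avoid the R API.
struct FastRng {
  uint64_t s[4];
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  static inline uint64_t splitmix(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit FastRng(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(seed);
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {            // (0, 1]
    return ((next() >> 11) + 1) * 1.1102230246251565e-16;
  }
  inline double expo() { return -std::log(unif()); }

  // ziggurat normal sampler (128 layers)
  static double zx[130], zr[129];
  static bool zinit;
  static void zig_setup() {
    const double R = 3.442619855899, V = 9.91256303526217e-3;
    double f = std::exp(-0.5 * R * R);
    zx[0] = V / f; zx[1] = R; zx[128] = 0.0;
    for (int i = 2; i < 128; ++i) {
      zx[i] = std::sqrt(-2.0 * std::log(V / zx[i - 1] + f));
      f = std::exp(-0.5 * zx[i] * zx[i]);
    }
    for (int i = 0; i < 128; ++i) zr[i] = zx[i + 1] / zx[i];
    zinit = true;
  }
  inline double norm() {
    for (;;) {
      uint64_t b = next();
      int i = (int)(b & 127);
      double u = 2.0 * (((b >> 11) + 1) * 1.1102230246251565e-16) - 1.0;
      if (std::fabs(u) < zr[i]) return u * zx[i];
      if (i == 0) {                 // tail beyond R
        const double R = 3.442619855899;
        double x, y;
        do { x = std::log(unif()) / R; y = std::log(unif()); }
        while (-2.0 * y < x * x);
        return u < 0 ? x - R : R - x;
      }
      double x = u * zx[i];
      double f0 = std::exp(-0.5 * (zx[i] * zx[i] - x * x));
      double f1 = std::exp(-0.5 * (zx[i + 1] * zx[i + 1] - x * x));
      if (f1 + unif() * (f0 - f1) < 1.0) return x;
    }
  }
};
double FastRng::zx[130];
double FastRng::zr[129];
bool FastRng::zinit = false;

static FastRng make_engine() {
  if (!FastRng::zinit) FastRng::zig_setup();
  uint64_t hi = (uint64_t)std::floor(unif_rand() * 4294967296.0);
  uint64_t lo = (uint64_t)std::floor(unif_rand() * 4294967296.0);
  return FastRng((hi << 32) ^ lo);
}

// Continuous-time random walk with per-visit reaction probability p at the
// target.  Adjacency in CSR form (0-based).  The Bernoulli trial is drawn on
// each arrival at the target and, on success, the reaction completes at the
// end of that residence, so every visit contributes its residence time.
// [[Rcpp::export]]
List cpp_sample_reaction_times(IntegerVector offsets, IntegerVector neigh,
                               double w, int target, IntegerVector starts,
                               double p, double t_max) {
  int n = starts.size();
  NumericVector times(n);
  LogicalVector censored(n);
  FastRng rng = make_engine();
  for (int wk = 0; wk < n; ++wk) {
    int i = starts[wk];
    double t = 0.0;
    bool done = false, cens = false;
    while (!done) {
      bool react = (i == target) && (rng.unif() < p);
      int deg = offsets[i + 1] - offsets[i];
      t += rng.expo() / (w * deg);
      if (t >= t_max) { cens = true; break; }
      if (react) { done = true; break; }
      i = neigh[offsets[i] + (int)(rng.unif() * deg)];
    }
    times[wk] = cens ? t_max : t;
    censored[wk] = cens;
  }
  return List::create(_["time"] = times, _["censored"] = censored);
}

// First return time to the target: start from a uniformly chosen neighbour
// of the target (i.e. just after a departure) and measure the time until the
// next arrival, including the residence at the target on that arrival.
// [[Rcpp::export]]
NumericVector cpp_sample_return_times(IntegerVector offsets, IntegerVector neigh,
                                      double w, int target, int n) {
  NumericVector times(n);
  FastRng rng = make_engine();
  int tdeg = offsets[target + 1] - offsets[target];
  for (int wk = 0; wk < n; ++wk) {
    int i = neigh[offsets[target] + (int)(rng.unif() * tdeg)];
    double t = 0.0;
    while (true) {
      int deg = offsets[i + 1] - offsets[i];
      t += rng.expo() / (w * deg);
      if (i == target) break;
      i = neigh[offsets[i] + (int)(rng.unif() * deg)];
    }
    times[wk] = t;
  }
  return times;
}

// Accumulated occupation time per site over a long trajectory (no target),
// used to check the uniform stationary distribution.
// [[Rcpp::export]]
NumericVector cpp_occupation_times(IntegerVector offsets, IntegerVector neigh,
                                   double w, int start, double t_total) {
  int N = offsets.size() - 1;
  NumericVector occ(N);
  FastRng rng = make_engine();
  int i = start;
  double t = 0.0;
  while (t < t_total) {
    int deg = offsets[i + 1] - offsets[i];
    double res = rng.expo() / (w * deg);
    if (t + res > t_total) res = t_total - t;
    occ[i] += res;
    t += res;
    i = neigh[offsets[i] + (int)(rng.unif() * deg)];
  }
  return occ;
}

// ---- Brownian dynamics in star-shaped confining domains -------------------

// shape: 0 = ball (f == 1), 1 = domain A, 2 = domain B.
// In 2D the boundary is r(theta) = R f(theta) with theta the usual polar
// angle; in 3D the domain is the solid of revolution of the 2D curve about
// the vertical axis, so f is evaluated at asin(z / r).
static inline double fshape(int shape, double ang) {
  if (shape == 1) { double c = std::cos(ang); return 1.6 * (1.0 + 0.5 * c * c); }
  if (shape == 2) return 1.6 * (1.0 + 0.1 * std::sin(ang) + 0.3 * std::sin(3.0 * ang));
  return 1.0;
}

static inline double dfshape(int shape, double ang) {
  if (shape == 1) return -1.6 * std::sin(ang) * std::cos(ang);
  if (shape == 2) return 1.6 * (0.1 * std::cos(ang) + 0.9 * std::cos(3.0 * ang));
  return 0.0;
}

// Trig-free evaluation of R f(theta) at a point: with s = sin(theta) and
// cos^2(theta) available directly from the coordinates, f_A needs only
// cos^2 and f_B needs sin(3 theta) = 3 s - 4 s^3.
static inline double boundary_radius(int shape, int dim, double R,
                                     const double* x, double r) {
  if (shape == 0) return R;
  double s, c2;
  if (dim == 2) { s = x[1] / r; c2 = x[0] * x[0] / (r * r); }
  else { s = x[2] / r; c2 = 1.0 - s * s; }
  if (shape == 1) return R * 1.6 * (1.0 + 0.5 * c2);
  return R * 1.6 * (1.0 + 0.1 * s + 0.3 * (3.0 - 4.0 * s * s) * s);
}

// signed level function g < 0 inside the domain
static inline double level_g(int shape, int dim, double R, const double* p) {
  double r2 = 0.0;
  for (int d = 0; d < dim; ++d) r2 += p[d] * p[d];
  double r = std::sqrt(r2);
  if (r == 0.0) return -R;
  return r - boundary_radius(shape, dim, R, p, r);
}

// outward normal of the level set r = R f(theta) at point p (unnormalized):
// grad g = p/r - R f'(theta) grad theta
static inline void level_grad(int shape, int dim, double R, const double* p,
                              double* n) {
  double r2 = 0.0;
  for (int d = 0; d < dim; ++d) r2 += p[d] * p[d];
  double r = std::sqrt(r2);
  if (shape == 0) { for (int d = 0; d < dim; ++d) n[d] = p[d] / r; return; }
  if (dim == 2) {
    double ang = std::atan2(p[1], p[0]);
    double fp = R * dfshape(shape, ang);
    n[0] = p[0] / r + fp * p[1] / r2;
    n[1] = p[1] / r - fp * p[0] / r2;
  } else {
    double rho = std::sqrt(p[0] * p[0] + p[1] * p[1]);
    double ang = std::asin(std::max(-1.0, std::min(1.0, p[2] / r)));
    double fp = R * dfshape(shape, ang);
    if (rho < 1e-12 * r) {             // on the axis: f'(+-pi/2) = 0 here
      for (int d = 0; d < dim; ++d) n[d] = p[d] / r;
      return;
    }
    n[0] = p[0] / r + fp * p[2] * p[0] / (rho * r2);
    n[1] = p[1] / r + fp * p[2] * p[1] / (rho * r2);
    n[2] = p[2] / r - fp * (1.0 / rho - p[2] * p[2] / (rho * r2));
  }
}

// Specular reflection of the segment x -> y across the boundary: locate the
// crossing by bisection on the level function, then mirror the overshoot
// across the local tangent plane.  Falls back to rejecting the move (y := x)
// if the reflected point is still outside (sharp concave spots).
static inline void reflect_specular(int shape, int dim, double R,
                                    const double* x, double* y) {
  double lo = 0.0, hi = 1.0, c[3], n[3];
  for (int it = 0; it < 30; ++it) {
    double mid = 0.5 * (lo + hi);
    for (int d = 0; d < dim; ++d) c[d] = x[d] + mid * (y[d] - x[d]);
    if (level_g(shape, dim, R, c) < 0.0) lo = mid; else hi = mid;
  }
  for (int d = 0; d < dim; ++d) c[d] = x[d] + lo * (y[d] - x[d]);
  level_grad(shape, dim, R, c, n);
  double nn = 0.0, dp = 0.0;
  for (int d = 0; d < dim; ++d) nn += n[d] * n[d];
  for (int d = 0; d < dim; ++d) dp += (y[d] - c[d]) * n[d];
  double yr[3];
  for (int d = 0; d < dim; ++d) yr[d] = y[d] - 2.0 * dp * n[d] / nn;
  if (level_g(shape, dim, R, yr) < 0.0) {
    for (int d = 0; d < dim; ++d) y[d] = yr[d];
  } else {
    for (int d = 0; d < dim; ++d) y[d] = x[d];  // reject the move
  }
}

// Euler-Maruyama walk with an imperfect spherical target at the origin.
// model: 0 = sink (penetrable, kill rate k inside), 1 = Robin (impenetrable,
// reaction probability p_react per reflection), 2 = perfectly absorbing.
// Outer boundary: radial mirror across r = R f(theta); a proposal still
// outside after mirroring is rejected (walker stays put).
// [[Rcpp::export]]
List cpp_brownian_times(int shape, int dim, double R, double a, int model,
                        double rate, double D, double dt,
                        NumericMatrix starts, double t_max) {
  int n = starts.nrow();
  NumericVector times(n);
  LogicalVector censored(n);
  FastRng rng = make_engine();
  double sig = std::sqrt(2.0 * D * dt);
  double p_react = 0.0, p_kill = 0.0;
  if (model == 1) p_react = rate * std::sqrt(M_PI * dt / D);
  if (model == 0) p_kill = 1.0 - std::exp(-rate * dt);
  // quick-reject radius below which the outer boundary cannot be crossed
  double fmin = 1.0;
  if (shape == 1) fmin = 1.6;
  if (shape == 2) {
    fmin = 10.0;
    for (int j = 0; j < 2000; ++j) {
      double v = fshape(2, -M_PI + 2.0 * M_PI * j / 1999.0);
      if (v < fmin) fmin = v;
    }
  }
  double r_safe = R * fmin;
  for (int wk = 0; wk < n; ++wk) {
    double x[3] = {0.0, 0.0, 0.0};
    for (int d = 0; d < dim; ++d) x[d] = starts(wk, d);
    double t = 0.0;
    bool done = false, cens = false;
    while (!done) {
      double y[3] = {0.0, 0.0, 0.0};
      for (int d = 0; d < dim; ++d) y[d] = x[d] + sig * rng.norm();
      double r2 = 0.0;
      for (int d = 0; d < dim; ++d) r2 += y[d] * y[d];
      double r = std::sqrt(r2);
      // outer boundary: specular reflection across the local normal
      if (r > r_safe) {
        double rb = boundary_radius(shape, dim, R, y, r);
        if (r > rb) {
          reflect_specular(shape, dim, R, x, y);
          r2 = 0.0;
          for (int d = 0; d < dim; ++d) r2 += y[d] * y[d];
          r = std::sqrt(r2);
        }
      }
      // target
      if (model == 1 || model == 2) {
        if (r < a) {
          if (model == 2 || rng.unif() < p_react) { t += dt; done = true; break; }
          double rn = 2.0 * a - r;
          double sc = (r > 0.0) ? rn / r : 0.0;
          for (int d = 0; d < dim; ++d) y[d] *= sc;
          r = rn;
        }
      } else { // sink
        if (r < a && rng.unif() < p_kill) { t += dt; done = true; break; }
      }
      t += dt;
      for (int d = 0; d < dim; ++d) x[d] = y[d];
      if (t >= t_max) { cens = true; break; }
    }
    times[wk] = cens ? t_max : t;
    censored[wk] = cens;
  }
  return List::create(_["time"] = times, _["censored"] = censored);
}

// Specular boundary reflection exposed to the R-level geometry helpers.
// [[Rcpp::export]]
NumericVector cpp_reflect_specular(int shape, int dim, double R,
                                   NumericVector from, NumericVector to) {
  double x[3] = {0.0, 0.0, 0.0}, y[3] = {0.0, 0.0, 0.0};
  for (int d = 0; d < dim; ++d) { x[d] = from[d]; y[d] = to[d]; }
  if (level_g(shape, dim, R, y) >= 0.0) reflect_specular(shape, dim, R, x, y);
  NumericVector out(dim);
  for (int d = 0; d < dim; ++d) out[d] = y[d];
  return out;
}

// Point-in-domain test used by the R-level geometry helpers.
// [[Rcpp::export]]
LogicalVector cpp_inside_domain(int shape, int dim, double R, NumericMatrix x) {
  int n = x.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    double v[3] = {0.0, 0.0, 0.0};
    double r2 = 0.0;
    for (int d = 0; d < dim; ++d) { v[d] = x(i, d); r2 += v[d] * v[d]; }
    double r = std::sqrt(r2);
    out[i] = (r == 0.0) || (r < boundary_radius(shape, dim, R, v, r));
  }
  return out;
}
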