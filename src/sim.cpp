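// Euler-Maruyama core for the two-stage (evidence -> leaky motor) accumulator
// and the standard drift diffusion model. Per-trial counter-based seeding so
// that common-random-number ladders and bit-reproducibility are cheap.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline std::uint64_t splitmix64(std::uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// model: 0 = LIT (absorption on motor path y), 1 = DDM (absorption on x).
// Collapse rate c shrinks the bound separation linearly: A(t) = a - c*t.
// stack_pre/stack_post > 0 requests response-locked snippets around the
// threshold crossing; trials keep integrating for stack_post steps after
// absorption so post-response samples exist. stack_mode selects which
// signals are stored (0 = both, 1 = x only, 2 = y only) so 100k-trial
// ensembles do not pay for matrices they never read.
// [[Rcpp::export]]
List cpp_simulate(int n_trials, double dt, int nsteps, double v, double sigma,
                  double x0, double a, double lam, double c, int model,
                  bool keep_paths, int stack_pre, int stack_post,
                  double seed, int stack_mode = 0) {
  const bool lit = (model == 0);
  const bool pure = !R_finite(lam);   // lambda = Inf sentinel: y == x
  NumericVector fpt(n_trials, NA_REAL);
  IntegerVector boundary(n_trials, 0); // +1 upper, -1 lower, 0 censored
  NumericMatrix xp, yp, xs, ys;
  const bool stack = (stack_pre > 0 || stack_post > 0);
  const int slen = stack ? (stack_pre + stack_post + 1) : 0;
  if (keep_paths) {
    xp = NumericMatrix(n_trials, nsteps + 1);
    std::fill(xp.begin(), xp.end(), NA_REAL);
    yp = NumericMatrix(n_trials, nsteps + 1);
    std::fill(yp.begin(), yp.end(), NA_REAL);
  }
  const bool want_x = stack && stack_mode != 2;
  const bool want_y = stack && stack_mode != 1;
  if (want_x) {
    xs = NumericMatrix(n_trials, slen);
    std::fill(xs.begin(), xs.end(), NA_REAL);
  }
  if (want_y) {
    ys = NumericMatrix(n_trials, slen);
    std::fill(ys.begin(), ys.end(), NA_REAL);
  }
  const double sdt = sigma * std::sqrt(dt);
  std::vector<double> xbuf, ybuf;
  const std::uint64_t base = (std::uint64_t)(seed);
  for (int i = 0; i < n_trials; ++i) {
    std::mt19937_64 rng(splitmix64(base + 0x51ED2701ULL * (std::uint64_t)(i + 1)));
    std::normal_distribution<double> norm(0.0, 1.0);
    double x = x0, y = x0;
    int kcross = -1;
    int sgn = 0;
    if (keep_paths) { xp(i, 0) = x; yp(i, 0) = y; }
    const int extra = stack ? stack_post : 0;
    if (stack) {
      xbuf.assign(nsteps + 1 + extra, NA_REAL);
      ybuf.assign(nsteps + 1 + extra, NA_REAL);
      xbuf[0] = x; ybuf[0] = y;
    }
    int k = 1;
    for (; k <= nsteps; ++k) {
      double xn = x + v * dt + sdt * norm(rng);
      double yn;
      if (pure) yn = xn;
      else yn = y + lam * (x - y) * dt;
      x = xn; y = yn;
      if (keep_paths) { xp(i, k) = x; yp(i, k) = y; }
      if (stack) { xbuf[k] = x; ybuf[k] = y; }
      double half = 0.5 * (a - c * (k * dt));
      if (half <= 0.0) half = 0.0;
      double z = lit ? y : x;
      if (z >= half) { kcross = k; sgn = 1; break; }
      if (z <= -half) { kcross = k; sgn = -1; break; }
    }
    if (kcross > 0) {
      fpt[i] = kcross * dt;
      boundary[i] = sgn;
      if (stack) {
        // free-running continuation past the crossing for post-response samples
        for (int j = kcross + 1; j <= kcross + extra && j < (int)xbuf.size(); ++j) {
          double xn = x + v * dt + sdt * norm(rng);
          double yn = pure ? xn : (y + lam * (x - y) * dt);
          x = xn; y = yn;
          xbuf[j] = x; ybuf[j] = y;
        }
        for (int s = 0; s < slen; ++s) {
          int idx = kcross - stack_pre + s;
          if (idx >= 0 && idx < (int)xbuf.size()) {
            if (want_x) xs(i, s) = xbuf[idx];
            if (want_y) ys(i, s) = ybuf[idx];
          }
        }
      }
    }
  }
  List out = List::create(_["fpt"] = fpt, _["boundary"] = boundary);
  if (keep_paths) { out["x"] = xp; out["y"] = yp; }
  if (want_x) out["x_stack"] = xs;
  if (want_y) out["y_stack"] = ys;
  return out;
}
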