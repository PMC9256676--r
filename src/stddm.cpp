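#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>
using namespace Rcpp;

// First-passage-time machinery for Wiener diffusion with drift between two
// absorbing boundaries, diffusion coefficient fixed at 1. Internal coordinates:
// boundaries at 0 and a (= 2B), start fraction w in (0,1) measured from the
// lower (reject) boundary; upper crossing = accept. Decision time tau excludes
// non-decision time.

static const double SERIES_EPS = 1e-9;   // adaptive truncation threshold
static const double U_SWITCH  = 0.35;    // small/large-time series switch (t/a^2)

// ---- driftless lower-boundary FPT density phi(u, w), u = tau / a^2 ----------
// f_lower(tau; v,a,w) = exp(-v*a*w - v^2*tau/2) * phi(tau/a^2, w) / a^2

static double phi_small(double u, double w) {
  // method-of-images series, converges fast for small u
  double s = w * std::exp(-w * w / (2.0 * u));
  for (int k = 1; k < 200; ++k) {
    double wp = w + 2.0 * k, wm = w - 2.0 * k;
    double t1 = wp * std::exp(-wp * wp / (2.0 * u));
    double t2 = wm * std::exp(-wm * wm / (2.0 * u));
    s += t1 + t2;
    if (std::fabs(t1) + std::fabs(t2) < SERIES_EPS * 1e-3) break;
  }
  return s / std::sqrt(2.0 * M_PI * u * u * u);
}

static double phi_large(double u, double w) {
  // spectral series, converges fast for large u
  double s = 0.0;
  for (int k = 1; k < 200; ++k) {
    double term = k * std::exp(-k * k * M_PI * M_PI * u / 2.0) *
                  std::sin(k * M_PI * w);
    s += term;
    if (k * std::exp(-k * k * M_PI * M_PI * u / 2.0) < SERIES_EPS * 1e-3) break;
  }
  return M_PI * s;
}

static double wfpt_lower_raw(double tau, double v, double a, double w) {
  if (tau <= 0.0 || a <= 0.0 || w <= 0.0 || w >= 1.0) return 0.0;
  double u = tau / (a * a);
  double phi = (u < U_SWITCH) ? phi_small(u, w) : phi_large(u, w);
  if (phi <= 0.0) return 0.0;
  double lp = -v * a * w - 0.5 * v * v * tau - 2.0 * std::log(a);
  return std::exp(lp) * phi;
}

static double wfpt_dens(double tau, double v, double a, double w, bool upper) {
  return upper ? wfpt_lower_raw(tau, -v, a, 1.0 - w)
               : wfpt_lower_raw(tau, v, a, w);
}

// ---- transition density of surviving paths ---------------------------------
// p(x, t | x0) with absorption at 0 and a, drift v; method of images for
// small t/a^2, spectral otherwise.

static double trans_dens_one(double x, double x0, double t, double v, double a) {
  if (x <= 0.0 || x >= a || t <= 0.0) return 0.0;
  double u = t / (a * a), q;
  if (u < 0.15) {
    double s = 0.0;
    for (int k = 0; k < 100; ++k) {
      double contrib = 0.0;
      // images at shifts +2ka and -2ka (k = 0 is the direct pair)
      double d1 = x - x0 - 2.0 * k * a, d2 = x + x0 - 2.0 * k * a;
      contrib += std::exp(-d1 * d1 / (2.0 * t)) - std::exp(-d2 * d2 / (2.0 * t));
      if (k > 0) {
        double d3 = x - x0 + 2.0 * k * a, d4 = x + x0 + 2.0 * k * a;
        contrib += std::exp(-d3 * d3 / (2.0 * t)) - std::exp(-d4 * d4 / (2.0 * t));
      }
      s += contrib;
      if (k > 0 && std::fabs(contrib) < 1e-14) break;
    }
    q = s / std::sqrt(2.0 * M_PI * t);
  } else {
    double s = 0.0;
    for (int k = 1; k < 200; ++k) {
      double decay = std::exp(-k * k * M_PI * M_PI * u / 2.0);
      s += decay * std::sin(k * M_PI * x0 / a) * std::sin(k * M_PI * x / a);
      if (decay < 1e-14) break;
    }
    q = 2.0 * s / a;
  }
  if (q < 0.0) q = 0.0;  // roundoff guard
  return q * std::exp(v * (x - x0) - 0.5 * v * v * t);
}

// ---- Gauss-Legendre nodes on (-1, 1), cached by order -----------------------

static std::map<int, std::pair<std::vector<double>, std::vector<double> > > gl_cache;

static void gl_nodes(int n, std::vector<double>& xs, std::vector<double>& ws) {
  std::map<int, std::pair<std::vector<double>, std::vector<double> > >::iterator
    it = gl_cache.find(n);
  if (it != gl_cache.end()) { xs = it->second.first; ws = it->second.second; return; }
  xs.assign(n, 0.0); ws.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double x = std::cos(M_PI * (i + 0.75) / (n + 0.5));  // Chebyshev start
    for (int iter = 0; iter < 100; ++iter) {
      double p0 = 1.0, p1 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p2 = p1; p1 = p0;
        p0 = ((2.0 * j + 1.0) * x * p1 - j * p2) / (j + 1.0);
      }
      double dp = n * (x * p0 - p1) / (x * x - 1.0);
      double dx = p0 / dp;
      x -= dx;
      if (std::fabs(dx) < 1e-15) break;
    }
    double p0 = 1.0, p1 = 0.0;
    for (int j = 0; j < n; ++j) {
      double p2 = p1; p1 = p0;
      p0 = ((2.0 * j + 1.0) * x * p1 - j * p2) / (j + 1.0);
    }
    double dp = n * (x * p0 - p1) / (x * x - 1.0);
    xs[i] = x;
    ws[i] = 2.0 / ((1.0 - x * x) * dp * dp);
  }
  gl_cache[n] = std::make_pair(xs, ws);
}

// ---- piecewise-constant-drift FPT density -----------------------------------
// drift v1 on (0, t1), v2 afterwards; quad 0 = trapezoid grid, 1 = Gauss-Legendre

static double piecewise_fpt(double tau, double v1, double v2, double t1,
                            double a, double w, bool upper,
                            int quad, int n_nodes) {
  if (tau <= 0.0) return 0.0;
  if (t1 <= 1e-12) return wfpt_dens(tau, v2, a, w, upper);
  if (tau <= t1)   return wfpt_dens(tau, v1, a, w, upper);
  double x0 = w * a, rem = tau - t1, s = 0.0;
  // just past the change point the drift switch is negligible and the spatial
  // quadrature cannot resolve the boundary layer; use the first-segment form
  if (rem < 1e-3) return wfpt_dens(tau, v1, a, w, upper);
  // a very short first segment concentrates the entry-state mass in a spike
  // narrower than the quadrature resolution; propagate it as a drift shift
  // of the starting point instead (exact in the t1 -> 0 limit)
  double t1_min = (quad == 1) ? 0.02
                              : std::max(1e-3, std::pow(3.0 * a / n_nodes, 2));
  if (t1 < t1_min) {
    double x1 = x0 + v1 * t1;
    double lim = 1e-6 * a;
    if (x1 < lim) x1 = lim;
    if (x1 > a - lim) x1 = a - lim;
    return piecewise_fpt(rem, v2, v2, 0.0, a, x1 / a, upper, quad, n_nodes);
  }
  if (quad == 0) {
    // trapezoid with endpoints (integrand vanishes there)
    double h = a / (n_nodes - 1);
    for (int i = 1; i < n_nodes - 1; ++i) {
      double x = i * h;
      s += trans_dens_one(x, x0, t1, v1, a) *
           wfpt_dens(rem, v2, a, x / a, upper);
    }
    s *= h;
  } else {
    std::vector<double> xs, ws;
    gl_nodes(n_nodes, xs, ws);
    for (int i = 0; i < n_nodes; ++i) {
      double x = 0.5 * a * (xs[i] + 1.0);
      s += ws[i] * trans_dens_one(x, x0, t1, v1, a) *
           wfpt_dens(rem, v2, a, x / a, upper);
    }
    s *= 0.5 * a;
  }
  return s;
}

// ---- model drift schedules ---------------------------------------------------
// model_id: 0 = M0 (standard DDM), 1..4 = M1..M4. Fills v1 (before |s|),
// v2 (after |s|), t1 = |s| and start fraction w for one trial.

static void model_map(int model_id, double VP, double VM, double VA,
                      double wP, double wM, double wA, double s,
                      double B, double bias,
                      double& v1, double& v2, double& t1, double& w) {
  double P = wP * VP, M = wM * VM, A = wA * VA;
  w = bias;
  switch (model_id) {
  case 0:
    v1 = v2 = P + M; t1 = 0.0; break;
  case 1:
  case 2:
    v1 = (s > 0.0) ? P : M;
    v2 = P + M; t1 = std::fabs(s);
    if (model_id == 2) {
      // accumulated reward shifts the starting point (in evidence units),
      // clipped just inside the boundaries
      double e0 = (2.0 * bias - 1.0) * B + A;
      double lim = B * (1.0 - 1e-6);
      if (e0 >  lim) e0 =  lim;
      if (e0 < -lim) e0 = -lim;
      w = (e0 + B) / (2.0 * B);
    }
    break;
  case 3:
    v1 = A + ((s > 0.0) ? P : M);
    v2 = A + P + M; t1 = std::fabs(s); break;
  case 4:
    v1 = (s > 0.0) ? (P + M) : A;
    v2 = P + M + A; t1 = std::fabs(s); break;
  default:
    stop("invalid model id");
  }
  if (t1 <= 1e-12) { v1 = v2; t1 = 0.0; }
}

// =============================================================================
// exported interfaces
// =============================================================================

// [[Rcpp::export(name = ".wfpt_density_cpp")]]
NumericVector wfpt_density_cpp(NumericVector tau, double v, double a, double w,
                               bool upper) {
  int n = tau.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = wfpt_dens(tau[i], v, a, w, upper);
  return out;
}

// [[Rcpp::export(name = ".wfpt_prob_upper_cpp")]]
double wfpt_prob_upper_cpp(double v, double a, double w) {
  if (std::fabs(v) < 1e-12) return w;
  // absorption probability at the upper boundary for constant drift
  double num = 1.0 - std::exp(-2.0 * v * a * w);
  double den = 1.0 - std::exp(-2.0 * v * a);
  return num / den;
}

// [[Rcpp::export(name = ".trans_density_cpp")]]
NumericVector trans_density_cpp(NumericVector x, double x0, double t, double v,
                                double a) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = trans_dens_one(x[i], x0, t, v, a);
  return out;
}

// [[Rcpp::export(name = ".piecewise_fpt_cpp")]]
NumericVector piecewise_fpt_cpp(NumericVector tau, double v1, double v2,
                                double t1, double a, double w, bool upper,
                                int quad, int n_nodes) {
  int n = tau.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = piecewise_fpt(tau[i], v1, v2, t1, a, w, upper, quad, n_nodes);
  return out;
}

// [[Rcpp::export(name = ".stddm_trial_density_cpp")]]
NumericVector stddm_trial_density_cpp(NumericVector rt, IntegerVector accept,
                                      NumericVector VP, NumericVector VM,
                                      NumericVector VA,
                                      double wP, double wM, double wA, double s,
                                      double ndt, double B, double bias,
                                      int model_id, int quad, int n_nodes) {
  int n = rt.size();
  NumericVector out(n);
  double a = 2.0 * B;
  for (int i = 0; i < n; ++i) {
    double v1, v2, t1, w;
    model_map(model_id, VP[i], VM[i], VA[i], wP, wM, wA, s, B, bias,
              v1, v2, t1, w);
    double tau = rt[i] - ndt;
    out[i] = (tau <= 0.0) ? 0.0
      : piecewise_fpt(tau, v1, v2, t1, a, w, accept[i] == 1, quad, n_nodes);
  }
  return out;
}

// [[Rcpp::export(name = ".block_loglik_cpp")]]
double block_loglik_cpp(NumericVector rt, IntegerVector accept,
                        NumericVector VP, NumericVector VM, NumericVector VA,
                        double wP, double wM, double wA, double s,
                        double ndt, double B, double bias,
                        int model_id, int quad, int n_nodes) {
  if (B <= 0.0 || bias <= 0.0 || bias >= 1.0 || ndt < 0.0)
    return R_NegInf;
  int n = rt.size();
  double ll = 0.0, a = 2.0 * B;
  for (int i = 0; i < n; ++i) {
    double tau = rt[i] - ndt;
    if (tau <= 0.0) return R_NegInf;
    double v1, v2, t1, w;
    model_map(model_id, VP[i], VM[i], VA[i], wP, wM, wA, s, B, bias,
              v1, v2, t1, w);
    double d = piecewise_fpt(tau, v1, v2, t1, a, w, accept[i] == 1,
                             quad, n_nodes);
    if (d <= 0.0) return R_NegInf;
    ll += std::log(d);
  }
  return ll;
}

// ---- Euler-Maruyama simulator ------------------------------------------------
// Returns decision time tau (NA if no crossing by max_t) and boundary hit.
// Uses R's RNG so set.seed() governs reproducibility. A Brownian-bridge
// correction accounts for within-step boundary crossings that the discrete
// endpoints miss (removes the leading-order discretization bias).

static inline int em_step(double& x, double v, double a, double dt,
                          double sdt) {
  // returns 1 upper hit, 0 lower hit, -1 no hit; advances x
  double x0 = x;
  x += v * dt + sdt * norm_rand();
  if (x >= a) return 1;
  if (x <= 0.0) return 0;
  double p_up = std::exp(-2.0 * (a - x0) * (a - x) / dt);
  double p_dn = std::exp(-2.0 * x0 * x / dt);
  double u = unif_rand();
  if (u < p_up) return 1;
  if (u < p_up + p_dn) return 0;
  return -1;
}

// [[Rcpp::export(name = ".sim_fpt_cpp")]]
List sim_fpt_cpp(int n, double v1, double v2, double t1, double a, double w,
                 double dt, double max_t) {
  if (dt <= 0.0) stop("dt must be positive");
  NumericVector tau(n);
  IntegerVector hit(n);  // 1 = upper (accept), 0 = lower, NA = none
  double sdt = std::sqrt(dt);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double x = w * a, t = 0.0;
    int h = NA_INTEGER; double tt = NA_REAL;
    while (t < max_t) {
      double v = (t1 > 0.0 && t < t1) ? v1 : v2;
      int res = em_step(x, v, a, dt, sdt);
      t += dt;
      if (res >= 0) { h = res; tt = t; break; }
    }
    tau[i] = tt; hit[i] = h;
  }
  return List::create(Named("tau") = tau, Named("hit") = hit);
}

// Simulate one choice/RT per row of trial-level attributes at given parameters.
// rt includes non-decision time; rt > deadline or no crossing -> choice NA.

// [[Rcpp::export(name = ".sim_trials_cpp")]]
List sim_trials_cpp(NumericVector VP, NumericVector VM, NumericVector VA,
                    double wP, double wM, double wA, double s,
                    double ndt, double B, double bias, int model_id,
                    double dt, double max_t, double deadline) {
  if (dt <= 0.0) stop("dt must be positive");
  int n = VP.size();
  NumericVector rt(n);
  IntegerVector accept(n);
  double a = 2.0 * B, sdt = std::sqrt(dt);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double v1, v2, t1, w;
    model_map(model_id, VP[i], VM[i], VA[i], wP, wM, wA, s, B, bias,
              v1, v2, t1, w);
    double x = w * a, t = 0.0;
    int h = NA_INTEGER; double tt = NA_REAL;
    while (t < max_t) {
      double v = (t1 > 0.0 && t < t1) ? v1 : v2;
      int res = em_step(x, v, a, dt, sdt);
      t += dt;
      if (res >= 0) { h = res; tt = t; break; }
    }
    if (h == NA_INTEGER || tt + ndt > deadline) {
      rt[i] = NA_REAL; accept[i] = NA_INTEGER;
    } else {
      rt[i] = tt + ndt; accept[i] = h;
    }
  }
  return List::create(Named("rt") = rt, Named("accept") = accept);
}
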