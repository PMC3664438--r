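#include <Rcpp.h>
using namespace Rcpp;

// Circular 1-D world of summed Gaussian bumps, and the closed-loop
// forward-Euler integrator of the two-neuron CTRNN agent.  Kept in C++
// because evolutionary runs need ~1e5 trials of ~1e4 steps each.

static inline double wrap_pos(double p, double L) {
  double r = p - L * std::floor(p / L);
  if (r >= L) r -= L;          // guard against rounding at the seam
  if (r < 0.0) r = 0.0;
  return r;
}

// signed minimal wrapped distance in (-L/2, L/2]; sign convention:
// positive when p1 lies a short way "ahead" of p2 going backwards round
// the circle, fixed positive at the exact antipode.
static inline double wdist(double p1, double p2, double L) {
  double d = p1 - p2;
  d -= L * std::round(d / L);    // nearest-image; exact when |d| < L/2
  if (d <= -L / 2.0) d += L;     // antipode fixed positive by convention
  else if (d > L / 2.0) d -= L;
  return d;
}

static inline double field_sum(double p, const NumericVector& c,
                               const NumericVector& h, const NumericVector& w,
                               double L) {
  double s = 0.0;
  for (int j = 0; j < c.size(); ++j) {
    double d = wdist(p, c[j], L);
    s += h[j] * std::exp(-d * d / (2.0 * w[j] * w[j]));
  }
  return s;
}

static inline double field_grad(double p, const NumericVector& c,
                                const NumericVector& h, const NumericVector& w,
                                double L) {
  double g = 0.0;
  for (int j = 0; j < c.size(); ++j) {
    double d = wdist(p, c[j], L);
    double w2 = w[j] * w[j];
    g += -h[j] * d / w2 * std::exp(-d * d / (2.0 * w2));
  }
  return g;
}

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export]]
NumericVector cpp_sense(NumericVector p, NumericVector c, NumericVector h,
                        NumericVector w, double L) {
  int n = p.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = field_sum(p[i], c, h, w, L);
    out[i] = s > 1.0 ? 1.0 : s;
  }
  return out;
}

// gradient of the clipped field: 0 wherever the summed field reaches the
// clip level, the analytic sum derivative elsewhere
// [[Rcpp::export]]
NumericVector cpp_sense_gradient(NumericVector p, NumericVector c,
                                 NumericVector h, NumericVector w, double L) {
  int n = p.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = field_sum(p[i], c, h, w, L);
    out[i] = s >= 1.0 ? 0.0 : field_grad(p[i], c, h, w, L);
  }
  return out;
}

// Closed-loop Euler integration.  At every stored sample: s = sense(p),
// v = motor output of the current state (or the clamp value), ds = v *
// sense_gradient(p) in analytic mode, then the state and position advance.
// ds_mode: 0 analytic, 1 backward finite difference (s_t - s_{t-dt})/dt.
// clamp: if finite, velocity is forced to this constant (open-loop hook).
// motor_sign: +1 normal wiring, -1 inverted motor mapping.
// store: if false, only the final sample is returned (fitness evaluation).
// [[Rcpp::export]]
List cpp_run_trial(double p0, double y10, double y20, NumericVector c,
                   NumericVector h, NumericVector w, double L, double w11,
                   double w21, double th1, double th2, double tau1,
                   double tau2, double gs, double vmax, double T, double dt,
                   int ds_mode, double clamp, bool clamped, double motor_sign,
                   bool store) {
  int n = (int)std::llround(T / dt);
  int m = store ? n + 1 : 1;
  NumericVector tv(m), pv(m), sv(m), dsv(m), y1v(m), y2v(m), vv(m);

  double p = wrap_pos(p0, L), y1 = y10, y2 = y20;
  double s_prev = 0.0;
  for (int k = 0; k <= n; ++k) {
    double s = field_sum(p, c, h, w, L);
    double g = s >= 1.0 ? 0.0 : field_grad(p, c, h, w, L);
    if (s > 1.0) s = 1.0;
    double v = clamped ? clamp : motor_sign * vmax * (2.0 * logistic(y2 + th2) - 1.0);
    double ds;
    if (ds_mode == 0) ds = v * g;
    else ds = (k == 0) ? 0.0 : (s - s_prev) / dt;
    s_prev = s;

    if (store) {
      tv[k] = k * dt; pv[k] = p; sv[k] = s; dsv[k] = ds;
      y1v[k] = y1; y2v[k] = y2; vv[k] = v;
    } else if (k == n) {
      tv[0] = k * dt; pv[0] = p; sv[0] = s; dsv[0] = ds;
      y1v[0] = y1; y2v[0] = y2; vv[0] = v;
    }
    if (k == n) break;

    double sig1 = logistic(y1 + th1);
    double dy1 = (-y1 + w11 * sig1 + gs * ds) / tau1;
    double dy2 = (-y2 + w21 * sig1) / tau2;
    y1 += dt * dy1;
    y2 += dt * dy2;
    p = wrap_pos(p + dt * v, L);
    if (!std::isfinite(y1) || !std::isfinite(y2) || !std::isfinite(p))
      stop("non-finite state at step %d (t = %g)", k + 1, (k + 1) * dt);
  }
  return List::create(_["t"] = tv, _["p"] = pv, _["s"] = sv, _["ds"] = dsv,
                      _["y1"] = y1v, _["y2"] = y2v, _["v"] = vv);
}
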