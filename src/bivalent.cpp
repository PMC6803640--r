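// Bivalent-analyte surface binding kinetics.
//
// Species (all in RU of immobilized ligand equivalents):
//   L   free immobilized ligand
//   AL  1:1 analyte-ligand complex
//   AL2 bridged complex (one analyte spanning two ligands)
//
//   dL/dt   = -(ka1*A*L - kd1*AL) - (ka2*AL*L - kd2*AL2)
//   dAL/dt  =  (ka1*A*L - kd1*AL) - (ka2*AL*L - kd2*AL2)
//   dAL2/dt =   ka2*AL*L - kd2*AL2
//
// A (molar) is piecewise constant: the injection concentration during the
// association phase, zero afterwards.  L + AL + 2*AL2 is conserved.
//
// Integrator: Dormand-Prince 5(4) with standard embedded error control.
// The system is smooth and only mildly stiff at SPR-typical rate constants;
// DP5 with tight tolerances keeps the conservation defect < 1e-6 * Rmax.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void rhs(double A, const double* k, const double* y, double* dy) {
  // k = {ka1, ka2, kd1, kd2}
  const double f1 = k[0] * A * y[0] - k[2] * y[1];
  const double f2 = k[1] * y[1] * y[0] - k[3] * y[2];
  dy[0] = -f1 - f2;
  dy[1] =  f1 - f2;
  dy[2] =  f2;
}

// Dormand-Prince coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// 4th-order embedded weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
                    e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

// Advance y from t to tend with constant analyte A.  Throws on step-size
// collapse (signalled to R as an integration failure).
static void advance(double* y, double t, double tend, double A,
                    const double* k, double rtol, double atol) {
  if (tend <= t) return;
  double h = std::min(0.1, tend - t);
  double k1[3], k2[3], k3[3], k4[3], k5[3], k6[3], k7[3], ytmp[3], y5[3];
  rhs(A, k, y, k1);
  const double hmin = 1e-12 * std::max(1.0, tend);
  // generous cap: legitimate SPR constants need a few tens of steps per
  // second of simulated time; blowing through this means the parameters
  // are in a pathologically stiff region
  const double max_steps = 5000.0 * (tend - t) + 20000.0;
  double nstep = 0;
  while (t < tend) {
    if (++nstep > max_steps)
      stop("integration failure: step count exceeded (rate constants too extreme)");
    if (h < hmin)
      stop("integration failure: step size underflow (stiff or extreme rate constants)");
    if (t + h > tend) h = tend - t;

    for (int i = 0; i < 3; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    rhs(A, k, ytmp, k2);
    for (int i = 0; i < 3; ++i) ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(A, k, ytmp, k3);
    for (int i = 0; i < 3; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(A, k, ytmp, k4);
    for (int i = 0; i < 3; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    rhs(A, k, ytmp, k5);
    for (int i = 0; i < 3; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    rhs(A, k, ytmp, k6);
    for (int i = 0; i < 3; ++i)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                          b5 * k5[i] + b6 * k6[i]);
    rhs(A, k, y5, k7);

    double err = 0.0;
    for (int i = 0; i < 3; ++i) {
      const double y4 = y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                                    e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      const double d = (y5[i] - y4) / sc;
      err += d * d;
    }
    err = std::sqrt(err / 3.0);

    if (err <= 1.0 || h <= hmin * 2) {
      t += h;
      for (int i = 0; i < 3; ++i) { y[i] = y5[i]; k1[i] = k7[i]; }  // FSAL
      if (!std::isfinite(y[0]) || !std::isfinite(y[1]) || !std::isfinite(y[2]))
        stop("integration failure: non-finite state (diverging solution)");
    }
    double fac = 0.9 * std::pow(err > 1e-14 ? err : 1e-14, -0.2);
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
  }
}

// Species trajectories (L, AL, AL2) at the requested sample times for one
// injection: analyte = conc for t <= t_assoc, zero after.
// [[Rcpp::export]]
NumericMatrix bivalent_states_cpp(NumericVector k4, double rmax, double conc,
                                  NumericVector times, double t_assoc,
                                  double rtol, double atol) {
  const int n = times.size();
  NumericMatrix out(n, 3);
  double y[3] = {rmax, 0.0, 0.0};
  double k[4] = {k4[0], k4[1], k4[2], k4[3]};
  double t = 0.0;
  bool dissoc = false;
  for (int j = 0; j < n; ++j) {
    double tt = times[j];
    if (tt < t) stop("times must be non-decreasing");
    if (!dissoc && tt > t_assoc) {
      advance(y, t, t_assoc, conc, k, rtol, atol);
      t = t_assoc;
      dissoc = true;
    }
    advance(y, t, tt, dissoc ? 0.0 : conc, k, rtol, atol);
    t = tt;
    out(j, 0) = y[0]; out(j, 1) = y[1]; out(j, 2) = y[2];
  }
  return out;
}

// Response matrix (AL + AL2, optionally + per-curve offset) for a set of
// injection concentrations on a shared time grid.  Used as the fast inner
// loop of the global fit.
// [[Rcpp::export]]
NumericMatrix bivalent_responses_cpp(NumericVector k4, double rmax,
                                     NumericVector conc, NumericVector times,
                                     double t_assoc, NumericVector offsets,
                                     double rtol, double atol) {
  const int n = times.size(), m = conc.size();
  NumericMatrix out(n, m);
  double k[4] = {k4[0], k4[1], k4[2], k4[3]};
  for (int c = 0; c < m; ++c) {
    double y[3] = {rmax, 0.0, 0.0};
    double t = 0.0;
    bool dissoc = false;
    const double off = offsets.size() == m ? offsets[c] : 0.0;
    for (int j = 0; j < n; ++j) {
      double tt = times[j];
      if (!dissoc && tt > t_assoc) {
        advance(y, t, t_assoc, conc[c], k, rtol, atol);
        t = t_assoc;
        dissoc = true;
      }
      advance(y, t, tt, dissoc ? 0.0 : conc[c], k, rtol, atol);
      t = tt;
      out(j, c) = y[1] + y[2] + off;
    }
  }
  return out;
}

// Summed squared residuals of the model against an observed response matrix
// (same grid/ordering as bivalent_responses_cpp); keeps the optimizer's
// objective entirely in compiled code.
// [[Rcpp::export]]
double bivalent_sse_cpp(NumericVector k4, double rmax, NumericVector conc,
                        NumericVector times, double t_assoc,
                        NumericVector offsets, NumericMatrix obs,
                        double rtol, double atol) {
  NumericMatrix fit = bivalent_responses_cpp(k4, rmax, conc, times, t_assoc,
                                             offsets, rtol, atol);
  double sse = 0.0;
  const int n = fit.nrow(), m = fit.ncol();
  for (int c = 0; c < m; ++c)
    for (int j = 0; j < n; ++j) {
      const double r = fit(j, c) - obs(j, c);
      sse += r * r;
    }
  return sse;
}
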