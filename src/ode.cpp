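// Compiled long-run outcome classification for the two-type mean-field
// system, used by phase-diagram scans. Dormand-Prince 5(4) with adaptive
// steps, early stopping once the state is stationary to tolerance.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  double b0, d0, dprime, nu, e0, alpha, beta, w;
};

inline void rhs2(const double y[2], double f[2], const Pars& p) {
  double xp = y[0], xm = y[1];
  double X = xp + xm;
  if (X <= 0) { f[0] = f[1] = 0.0; return; }
  double ab = p.alpha + p.beta - p.alpha * p.beta;
  double dd = p.d0 + 2.0 * p.dprime * p.nu * X;
  double bp = 0.5 * p.b0 * (xp * xp * ab + (p.alpha + p.beta) * xm * xp) / X;
  double bm = 0.5 * p.b0 *
    (xm * xm + (2.0 - p.alpha - p.beta) * xm * xp +
     (1.0 - p.alpha) * (1.0 - p.beta) * xp * xp) / X;
  f[0] = bp - xp * dd / p.w + p.e0 * xm;
  f[1] = bm - xm * dd - p.e0 * xm;
}

// labels: 1 loss, 2 fixation, 3 bimorphic, 4 host_extinction, 5 unresolved
int classify_core(const Pars& p, double init_frac, double eps,
                  double conv_tol, double t_cap, double extinct_density,
                  double rtol, double atol, double* out_state, double* out_t) {
  double xI = (0.5 * p.b0 - p.d0) / (2.0 * p.dprime * p.nu);
  out_state[0] = out_state[1] = 0.0;
  out_t[0] = 0.0;
  if (xI <= 0) return 4; // host not viable even without the symbiont

  if (p.w <= 0) {
    // limit of an unconditionally lethal symbiont: carriers never persist;
    // non-carriers see uptake as extra per-capita mortality e0
    double xeq = (0.5 * p.b0 - p.d0 - p.e0) / (2.0 * p.dprime * p.nu);
    if (xeq > eps) { out_state[1] = xeq; return 1; }
    return 4;
  }

  static const double a2[] = {1.0 / 5};
  static const double a3[] = {3.0 / 40, 9.0 / 40};
  static const double a4[] = {44.0 / 45, -56.0 / 15, 32.0 / 9};
  static const double a5[] = {19372.0 / 6561, -25360.0 / 2187,
                              64448.0 / 6561, -212.0 / 729};
  static const double a6[] = {9017.0 / 3168, -355.0 / 33, 46732.0 / 5247,
                              49.0 / 176, -5103.0 / 18656};
  static const double a7[] = {35.0 / 384, 0.0, 500.0 / 1113, 125.0 / 192,
                              -2187.0 / 6784, 11.0 / 84};
  static const double b4[] = {5179.0 / 57600, 0.0, 7571.0 / 16695,
                              393.0 / 640, -92097.0 / 339200,
                              187.0 / 2100, 1.0 / 40};
  const double* A[] = {a2, a3, a4, a5, a6, a7};

  double y[2] = {init_frac * xI, xI};
  double t = 0.0, h = 1e-3;
  const double hmax = 50.0;
  double k[7][2], ytmp[2], y5[2], y4[2], f[2];

  for (long iter = 0; iter < 100000000L; ++iter) {
    if (t >= t_cap) break;
    if (h > hmax) h = hmax;
    if (h > t_cap - t) h = t_cap - t;
    rhs2(y, k[0], p);
    for (int s = 0; s < 6; ++s) {
      ytmp[0] = y[0];
      ytmp[1] = y[1];
      for (int j = 0; j <= s; ++j) {
        ytmp[0] += h * A[s][j] * k[j][0];
        ytmp[1] += h * A[s][j] * k[j][1];
      }
      rhs2(ytmp, k[s + 1], p);
    }
    double e2 = 0.0;
    for (int i = 0; i < 2; ++i) {
      y5[i] = y[i];
      y4[i] = y[i];
      for (int j = 0; j < 7; ++j) {
        double kv = k[j][i];
        if (j < 6) y5[i] += h * a7[j] * kv; // b5 coefficients equal a7, b5[6]=0
        y4[i] += h * b4[j] * kv;
      }
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double d = (y5[i] - y4[i]) / sc;
      e2 += d * d;
    }
    double err = std::sqrt(e2 / 2.0);
    if (err <= 1.0 || h <= 1e-12) {
      t += h;
      y[0] = y5[0] < 0 ? 0.0 : y5[0];
      y[1] = y5[1] < 0 ? 0.0 : y5[1];
      double X = y[0] + y[1];
      if (X < eps) { out_state[0] = y[0]; out_state[1] = y[1]; out_t[0] = t; return 4; }
      rhs2(y, f, p);
      if (std::fabs(f[0]) < conv_tol * (1.0 + std::fabs(y[0])) &&
          std::fabs(f[1]) < conv_tol * (1.0 + std::fabs(y[1]))) {
        out_state[0] = y[0];
        out_state[1] = y[1];
        out_t[0] = t;
        if (X < extinct_density) return 4;
        if (y[1] < eps) return 2;
        if (y[0] < eps) return 1;
        return 3;
      }
    }
    double fac = err > 0 ? 0.9 * std::pow(err, -0.2) : 5.0;
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
  }
  out_state[0] = y[0];
  out_state[1] = y[1];
  out_t[0] = t;
  double X = y[0] + y[1];
  if (X < eps || X < extinct_density) return 4;
  if (y[1] < eps) return 2;
  if (y[0] < eps) return 1;
  return 5;
}

} // namespace

// [[Rcpp::export]]
List classify_two_cpp(double b0, double d0, double dprime, double nu,
                      double e0, double alpha, double beta, double w,
                      double init_frac, double eps, double conv_tol,
                      double t_cap, double extinct_density,
                      double rtol, double atol) {
  Pars p = {b0, d0, dprime, nu, e0, alpha, beta, w};
  double st[2], tt;
  int lab = classify_core(p, init_frac, eps, conv_tol, t_cap,
                          extinct_density, rtol, atol, st, &tt);
  return List::create(_["label"] = lab,
                      _["state"] = NumericVector::create(st[0], st[1]),
                      _["t"] = tt);
}

// [[Rcpp::export]]
IntegerMatrix classify_grid_cpp(NumericVector wv, NumericVector ev,
                                double b0, double d0, double dprime,
                                double nu, double alpha, double beta,
                                double init_frac, double eps,
                                double conv_tol, double t_cap,
                                double extinct_density,
                                double rtol, double atol) {
  IntegerMatrix out(wv.size(), ev.size());
  double st[2], tt;
  for (int j = 0; j < ev.size(); ++j) {
    for (int i = 0; i < wv.size(); ++i) {
      Pars p = {b0, d0, dprime, nu, ev[j], alpha, beta, wv[i]};
      out(i, j) = classify_core(p, init_frac, eps, conv_tol, t_cap,
                                extinct_density, rtol, atol, st, &tt);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
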