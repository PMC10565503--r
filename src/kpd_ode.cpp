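#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
#include <functional>

using namespace Rcpp;

// Structural K-PD model:
//   dA/dt  = -KDE * A            (virtual dose compartment, solved analytically)
//   IR     =  KDE * A
//   dR/dt  =  KS * (1 + IR/(EDK50 + IR)) * Tol - KD * R,  KS = BASE * KD
//   Tol    =  exp(-K * (t - clock_start)) for t > clock_start, else 1
// A(t) is a superposition of exponentials, so only R is integrated numerically.

namespace {

struct Rhs {
  double kde, kd, edk50, k_tol, base, clock_start;
  const std::vector<double>* dose_t;
  const std::vector<double>* dose_a;
  // only doses with index < n_active contribute on the current segment;
  // segments never contain a dose time in their interior
  size_t n_active;

  double operator()(double t, double R) const {
    double a = 0.0;
    for (size_t i = 0; i < n_active; ++i)
      a += (*dose_a)[i] * std::exp(-kde * (t - (*dose_t)[i]));
    double ir = kde * a;
    double stim = 1.0 + ir / (edk50 + ir);
    double tol = (t > clock_start) ? std::exp(-k_tol * (t - clock_start)) : 1.0;
    return base * kd * stim * tol - kd * R;
  }
};

// Cash-Karp embedded Runge-Kutta 4(5), scalar state, adaptive step
double advance(const Rhs& f, double t0, double t1, double R,
               double rtol, double atol) {
  if (t1 <= t0) return R;
  double t = t0;
  double h = t1 - t0;
  long guard = 0;
  while (t < t1) {
    if (++guard > 2000000L)
      stop("K-PD integrator failed to advance (too many steps near t=%g)", t);
    if (t + h > t1) h = t1 - t;
    double k1 = f(t, R);
    double k2 = f(t + 0.2 * h, R + h * (0.2 * k1));
    double k3 = f(t + 0.3 * h, R + h * (3.0 / 40.0 * k1 + 9.0 / 40.0 * k2));
    double k4 = f(t + 0.6 * h, R + h * (0.3 * k1 - 0.9 * k2 + 1.2 * k3));
    double k5 = f(t + h,       R + h * (-11.0 / 54.0 * k1 + 2.5 * k2
                                        - 70.0 / 27.0 * k3 + 35.0 / 27.0 * k4));
    double k6 = f(t + 0.875 * h,
                  R + h * (1631.0 / 55296.0 * k1 + 175.0 / 512.0 * k2
                           + 575.0 / 13824.0 * k3 + 44275.0 / 110592.0 * k4
                           + 253.0 / 4096.0 * k5));
    double R5 = R + h * (37.0 / 378.0 * k1 + 250.0 / 621.0 * k3
                         + 125.0 / 594.0 * k4 + 512.0 / 1771.0 * k6);
    double err = h * ((37.0 / 378.0 - 2825.0 / 27648.0) * k1
                      + (250.0 / 621.0 - 18575.0 / 48384.0) * k3
                      + (125.0 / 594.0 - 13525.0 / 55296.0) * k4
                      - (277.0 / 14336.0) * k5
                      + (512.0 / 1771.0 - 0.25) * k6);
    double sc = atol + rtol * std::max(std::fabs(R), std::fabs(R5));
    double e = std::fabs(err) / sc;
    if (e <= 1.0) {
      t += h;
      R = R5;
      double fac = (e > 1e-12) ? 0.9 * std::pow(e, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.2, 0.9 * std::pow(e, -0.25));
      if (h < 1e-12)
        stop("K-PD integrator step size underflow at t=%g", t);
    }
    if (!std::isfinite(R))
      stop("K-PD integrator produced a non-finite response at t=%g", t);
  }
  return R;
}

// response R at sorted output times; dose times sorted ascending
std::vector<double> simulate_response(const std::vector<double>& out_t,
                                      double kde, double kd, double edk50,
                                      double k_tol, double base,
                                      double clock_start,
                                      const std::vector<double>& dose_t,
                                      const std::vector<double>& dose_a,
                                      double rtol, double atol) {
  Rhs f{kde, kd, edk50, k_tol, base, clock_start, &dose_t, &dose_a, 0};
  const size_t n = out_t.size(), nd = dose_t.size();
  std::vector<double> out(n);
  double t_first_dose = nd ? dose_t[0] : std::numeric_limits<double>::infinity();
  // before both the first dose and the tolerance clock start the system sits
  // at its steady state R = BASE
  double t_act = std::min(clock_start, t_first_dose);
  double t = t_act, R = base;
  size_t di = 0;
  while (di < nd && dose_t[di] <= t_act) ++di;
  for (size_t i = 0; i < n; ++i) {
    double target = out_t[i];
    if (target <= t_act) { out[i] = base; continue; }
    while (di < nd && dose_t[di] < target) {
      double tk = dose_t[di];
      if (tk > t) {
        f.n_active = di;
        R = advance(f, t, tk, R, rtol, atol);
        t = tk;
      }
      ++di;  // dose becomes active for subsequent segments
    }
    f.n_active = di;
    R = advance(f, t, target, R, rtol, atol);
    t = target;
    out[i] = R;
  }
  return out;
}

double golden_min(const std::function<double(double)>& g,
                  double lo, double hi, double tol) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = g(x1), f2 = g(x2);
  while (b - a > tol) {
    if (f1 < f2) {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a); f1 = g(x1);
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a); f2 = g(x2);
    }
  }
  return 0.5 * (a + b);
}

struct ArmDat {
  std::vector<double> obs_t, dv, dose_t, dose_a;
  double base, clock_start, weight;
};

// conditional -2 log-likelihood of one arm given eta (exponential IIV on EDK50)
double cond_m2ll(const ArmDat& A, double kde, double kd, double edk50,
                 double k_tol, double omega2, double sigma2, double eta,
                 bool proportional, double rtol, double atol) {
  double e50 = edk50 * std::exp(eta);
  std::vector<double> pred = simulate_response(
      A.obs_t, kde, kd, e50, k_tol, A.base, A.clock_start,
      A.dose_t, A.dose_a, rtol, atol);
  double out = 0.0;
  const double two_pi = 2.0 * M_PI;
  for (size_t j = 0; j < pred.size(); ++j) {
    double var = proportional ? sigma2 * pred[j] * pred[j] : sigma2;
    var /= A.weight;
    double r = A.dv[j] - pred[j];
    out += std::log(two_pi * var) + r * r / var;
  }
  if (omega2 > 0.0)
    out += eta * eta / omega2 + std::log(two_pi * omega2);
  return out;
}

}  // namespace

// [[Rcpp::export]]
NumericVector kpd_response_cpp(NumericVector times, NumericVector pars,
                               NumericVector dose_t, NumericVector dose_a,
                               double clock_start, double rtol, double atol) {
  std::vector<double> out_t(times.begin(), times.end());
  std::vector<double> dt(dose_t.begin(), dose_t.end());
  std::vector<double> da(dose_a.begin(), dose_a.end());
  std::vector<double> r = simulate_response(
      out_t, pars[0], pars[1], pars[2], pars[3], pars[4],
      clock_start, dt, da, rtol, atol);
  return NumericVector(r.begin(), r.end());
}

// responses for a batch of EDK50 multipliers (exp(eta) draws); one column per draw
// [[Rcpp::export]]
NumericMatrix kpd_response_batch_cpp(NumericVector times, NumericVector pars,
                                     NumericVector dose_t, NumericVector dose_a,
                                     double clock_start,
                                     NumericVector edk50_mult,
                                     double rtol, double atol) {
  std::vector<double> out_t(times.begin(), times.end());
  std::vector<double> dt(dose_t.begin(), dose_t.end());
  std::vector<double> da(dose_a.begin(), dose_a.end());
  NumericMatrix out(times.size(), edk50_mult.size());
  for (int s = 0; s < edk50_mult.size(); ++s) {
    std::vector<double> r = simulate_response(
        out_t, pars[0], pars[1], pars[2] * edk50_mult[s], pars[3], pars[4],
        clock_start, dt, da, rtol, atol);
    for (int i = 0; i < times.size(); ++i) out(i, s) = r[i];
  }
  return out;
}

// Laplace approximation to the marginal -2 log-likelihood, summed over arms.
// theta = (kde, kd, edk50, k_tol). Each arm: list(obs_t, dv, dose_t, dose_a,
// base, clock_start, weight). eta_init supplies warm starts for the per-arm
// mode search (Newton with golden-section fallback).
// [[Rcpp::export]]
List kpd_laplace_cpp(NumericVector theta, double omega2, double sigma2,
                     List arms, NumericVector eta_init, bool proportional,
                     double rtol, double atol, double inner_tol) {
  const int na = arms.size();
  std::vector<ArmDat> A(na);
  for (int i = 0; i < na; ++i) {
    List a = arms[i];
    NumericVector ot = a["obs_t"], dv = a["dv"], dt = a["dose_t"], da = a["dose_a"];
    A[i].obs_t.assign(ot.begin(), ot.end());
    A[i].dv.assign(dv.begin(), dv.end());
    A[i].dose_t.assign(dt.begin(), dt.end());
    A[i].dose_a.assign(da.begin(), da.end());
    A[i].base = as<double>(a["base"]);
    A[i].clock_start = as<double>(a["clock_start"]);
    A[i].weight = as<double>(a["weight"]);
  }
  double kde = theta[0], kd = theta[1], edk50 = theta[2], k_tol = theta[3];

  NumericVector eta_hat(na), g_mode(na), curvature(na);
  LogicalVector ok(na);
  double total = 0.0;
  const bool pooled = !(omega2 > 1e-12);

  for (int i = 0; i < na; ++i) {
    const ArmDat& arm = A[i];
    std::function<double(double)> g = [&](double e) {
      return cond_m2ll(arm, kde, kd, edk50, k_tol, omega2, sigma2, e,
                       proportional, rtol, atol);
    };
    if (pooled) {
      double g0 = g(0.0);
      eta_hat[i] = 0.0; g_mode[i] = g0; curvature[i] = NA_REAL; ok[i] = true;
      total += g0;
      continue;
    }
    double eta = (i < eta_init.size() && std::isfinite(eta_init[i])) ? eta_init[i] : 0.0;
    if (std::fabs(eta) > 8.0) eta = 0.0;
    const double h = 1e-4;
    bool converged = false;
    double g0 = g(eta);
    for (int it = 0; it < 50; ++it) {
      double gp = g(eta + h), gm = g(eta - h);
      double d1 = (gp - gm) / (2.0 * h);
      double d2 = (gp - 2.0 * g0 + gm) / (h * h);
      if (!std::isfinite(d1) || !std::isfinite(d2) || d2 <= 0.0) break;
      double step = d1 / d2;
      if (step > 2.0) step = 2.0;
      if (step < -2.0) step = -2.0;
      double enew = eta - step, gnew = g(enew);
      int bt = 0;
      while (gnew > g0 + 1e-12 && bt < 10) {
        step *= 0.5; enew = eta - step; gnew = g(enew); ++bt;
      }
      if (gnew > g0 + 1e-12) {  // could not descend: at (numerical) minimum
        converged = true;
        break;
      }
      eta = enew; g0 = gnew;
      if (!std::isfinite(eta) || std::fabs(eta) > 12.0) break;
      if (std::fabs(step) < inner_tol) { converged = true; break; }
    }
    if (!converged) {
      eta = golden_min(g, -8.0, 8.0, 1e-7);
      g0 = g(eta);
    }
    double hc = h;
    double gp = g(eta + hc), gm = g(eta - hc);
    double d2 = (gp - 2.0 * g0 + gm) / (hc * hc);
    if (!(d2 > 0.0)) {  // widen the stencil if curvature is lost in noise
      hc = 1e-2;
      gp = g(eta + hc); gm = g(eta - hc);
      d2 = (gp - 2.0 * g0 + gm) / (hc * hc);
    }
    eta_hat[i] = eta;
    g_mode[i] = g0;
    curvature[i] = d2;
    ok[i] = (d2 > 0.0) && std::isfinite(g0);
    if (ok[i])
      total += g0 + std::log(0.5 * d2 / (2.0 * M_PI));
    else
      total = NA_REAL;
  }

  return List::create(_["m2ll"] = total, _["eta"] = eta_hat,
                      _["g_mode"] = g_mode, _["curvature"] = curvature,
                      _["ok"] = ok);
}
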