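// Compiled core for the three-species Lotka-Volterra tumor model:
// RK4 integration under piecewise-constant dosing, closed-loop protocol
// simulation, and the Forward-Backward Sweep optimal-control inner loops.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  double r[3];
  double A[3][3];          // A[i][j]: effect of type j on type i
  double K3;               // carrying capacity of T-
  double ktp_int, ktp_sl;  // K_TP(lam) = ktp_int + ktp_sl * lam
  double mu_int, mu_sl;    // mu(lam)   = mu_int  + mu_sl  * lam
  double cap;              // viability cap on total burden
  double eps;              // tp_floor regularization for K_T+
  double snap;             // extinction snap threshold
};

Pars unpack(const List& p) {
  Pars q;
  NumericVector r = p["r"];
  NumericMatrix A = p["A"];
  for (int i = 0; i < 3; ++i) {
    q.r[i] = r[i];
    for (int j = 0; j < 3; ++j) q.A[i][j] = A(i, j);
  }
  q.K3 = as<double>(p["K_Tminus"]);
  NumericVector kl = p["K_TP_law"];
  q.ktp_int = kl[0]; q.ktp_sl = kl[1];
  NumericVector ml = p["mu_law"];
  q.mu_int = ml[0]; q.mu_sl = ml[1];
  q.cap  = as<double>(p["viability_cap"]);
  q.eps  = as<double>(p["tp_floor"]);
  q.snap = as<double>(p["extinction_snap"]);
  return q;
}

inline double mu_of(const Pars& p, double lam) { return p.mu_int + p.mu_sl * lam; }
inline double k2_of(const Pars& p, double lam) { return p.ktp_int + p.ktp_sl * lam; }

inline void rhs(const Pars& p, const double x[3], double lam, double dx[3]) {
  double m2 = x[1] > p.eps ? x[1] : p.eps;
  double K1 = mu_of(p, lam) * m2;
  double K2 = k2_of(p, lam);
  double S0 = p.A[0][0] * x[0] + p.A[0][1] * x[1] + p.A[0][2] * x[2];
  double S1 = p.A[1][0] * x[0] + p.A[1][1] * x[1] + p.A[1][2] * x[2];
  double S2 = p.A[2][0] * x[0] + p.A[2][1] * x[1] + p.A[2][2] * x[2];
  dx[0] = p.r[0] * x[0] * (1.0 - S0 / K1);
  dx[1] = p.r[1] * x[1] * (1.0 - S1 / K2);
  dx[2] = p.r[2] * x[2] * (1.0 - S2 / p.K3);
}

// Jacobian of the regularized vector field at (x, lam).
void jac(const Pars& p, const double x[3], double lam, double J[3][3]) {
  double mu = mu_of(p, lam);
  double m2 = x[1] > p.eps ? x[1] : p.eps;
  double K1 = mu * m2;
  double K2 = k2_of(p, lam);
  double S0 = p.A[0][0] * x[0] + p.A[0][1] * x[1] + p.A[0][2] * x[2];
  double S1 = p.A[1][0] * x[0] + p.A[1][1] * x[1] + p.A[1][2] * x[2];
  double S2 = p.A[2][0] * x[0] + p.A[2][1] * x[1] + p.A[2][2] * x[2];
  // row T+: K1 depends on x_TP unless the floor is active
  J[0][0] = p.r[0] * (1.0 - (S0 + p.A[0][0] * x[0]) / K1);
  if (x[1] > p.eps)
    J[0][1] = p.r[0] * x[0] * (S0 - p.A[0][1] * x[1]) / (mu * x[1] * x[1]);
  else
    J[0][1] = -p.r[0] * x[0] * p.A[0][1] / K1;
  J[0][2] = -p.r[0] * x[0] * p.A[0][2] / K1;
  // row TP
  J[1][0] = -p.r[1] * x[1] * p.A[1][0] / K2;
  J[1][1] = p.r[1] * (1.0 - (S1 + p.A[1][1] * x[1]) / K2);
  J[1][2] = -p.r[1] * x[1] * p.A[1][2] / K2;
  // row T-
  J[2][0] = -p.r[2] * x[2] * p.A[2][0] / p.K3;
  J[2][1] = -p.r[2] * x[2] * p.A[2][1] / p.K3;
  J[2][2] = p.r[2] * (1.0 - (S2 + p.A[2][2] * x[2]) / p.K3);
}

void jac_fd(const Pars& p, const double x[3], double lam, double J[3][3]) {
  for (int j = 0; j < 3; ++j) {
    double h = 1e-4 * std::max(1.0, std::fabs(x[j]));
    double xp[3] = {x[0], x[1], x[2]}, xm[3] = {x[0], x[1], x[2]};
    xp[j] += h; xm[j] -= h;
    double fp[3], fm[3];
    rhs(p, xp, lam, fp);
    rhs(p, xm, lam, fm);
    for (int i = 0; i < 3; ++i) J[i][j] = (fp[i] - fm[i]) / (2.0 * h);
  }
}

// One RK4 step with stage doses l0 (start), lm (midpoint), l1 (end).
inline void rk4_step(const Pars& p, double x[3], double dt,
                     double l0, double lm, double l1) {
  double k1[3], k2[3], k3[3], k4[3], tmp[3];
  rhs(p, x, l0, k1);
  for (int i = 0; i < 3; ++i) tmp[i] = x[i] + 0.5 * dt * k1[i];
  rhs(p, tmp, lm, k2);
  for (int i = 0; i < 3; ++i) tmp[i] = x[i] + 0.5 * dt * k2[i];
  rhs(p, tmp, lm, k3);
  for (int i = 0; i < 3; ++i) tmp[i] = x[i] + dt * k3[i];
  rhs(p, tmp, l1, k4);
  for (int i = 0; i < 3; ++i) {
    x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (x[i] < p.snap) x[i] = 0.0;  // clip below zero and snap extinct clones
  }
}

inline double dose_at(const NumericVector& bt, const NumericVector& bd, double t) {
  // piecewise-constant lookup: value of the last breakpoint <= t
  int lo = 0, hi = bt.size() - 1;
  if (t <= bt[0]) return bd[0];
  if (t >= bt[hi]) return bd[hi];
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (bt[mid] <= t) lo = mid; else hi = mid;
  }
  return bd[lo];
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_vector_field(NumericVector x, double lam, List params) {
  Pars p = unpack(params);
  double xx[3] = {x[0], x[1], x[2]}, dx[3];
  rhs(p, xx, lam, dx);
  return NumericVector::create(dx[0], dx[1], dx[2]);
}

// [[Rcpp::export]]
NumericMatrix cpp_jacobian(NumericVector x, double lam, List params,
                           bool finite_diff = false) {
  Pars p = unpack(params);
  double xx[3] = {x[0], x[1], x[2]}, J[3][3];
  if (finite_diff) jac_fd(p, xx, lam, J); else jac(p, xx, lam, J);
  NumericMatrix out(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = J[i][j];
  return out;
}

// Integrate under a piecewise-constant dose schedule on a fixed grid.
// [[Rcpp::export]]
List cpp_simulate(NumericVector x0, NumericVector break_times,
                  NumericVector break_doses, double t0, double tf, double dt,
                  List params, bool stop_on_breach) {
  Pars p = unpack(params);
  int n = (int)std::lround((tf - t0) / dt);
  NumericVector tg(n + 1), dose(n + 1);
  NumericMatrix X(n + 1, 3);
  double x[3] = {x0[0], x0[1], x0[2]};
  double breach = NA_REAL;
  int last = n;
  for (int k = 0; k <= n; ++k) {
    double t = t0 + k * dt;
    tg[k] = t;
    dose[k] = dose_at(break_times, break_doses, t);
    for (int i = 0; i < 3; ++i) X(k, i) = x[i];
    double tot = x[0] + x[1] + x[2];
    if (ISNA(breach) && tot > p.cap) {
      breach = t;
      if (stop_on_breach) { last = k; break; }
    }
    if (k == n) break;
    double l0 = dose[k];
    double l1 = dose_at(break_times, break_doses, t + dt);
    double lm = dose_at(break_times, break_doses, t + 0.5 * dt);
    rk4_step(p, x, dt, l0, lm, l1);
  }
  if (last < n) {
    tg = tg[Range(0, last)];
    dose = dose[Range(0, last)];
    X = X(Range(0, last), _);
  }
  return List::create(_["t"] = tg, _["x"] = X, _["dose"] = dose,
                      _["breach_time"] = breach);
}

// Closed-loop protocol simulation. kind: 0 = MTD, 1 = adaptive, 2 = titration.
// Doses live on the 0.1 grid (stored in integer tenths to avoid drift).
// [[Rcpp::export]]
List cpp_run_protocol(NumericVector x0, List params, int kind, double v_target,
                      double initial_dose, double t0, double tf, double dt,
                      double interval, double band_lo, double band_hi,
                      double dose_step, bool keep_path) {
  Pars p = unpack(params);
  int n = (int)std::lround((tf - t0) / dt);
  int meas_every = (int)std::lround(interval / dt);
  int step10 = (int)std::lround(dose_step * 10.0);
  double x[3] = {x0[0], x0[1], x0[2]};
  double v0 = x[0] + x[1] + x[2];
  int d10 = (int)std::lround(initial_dose * 10.0);
  bool phase_on = true;                       // adaptive starts dosing
  double cur = (kind == 0) ? 1.0 : (kind == 1 ? 1.0 : d10 / 10.0);
  double breach = NA_REAL;
  NumericVector tg, dose;
  NumericMatrix X;
  if (keep_path) {
    tg = NumericVector(n + 1);
    dose = NumericVector(n + 1);
    X = NumericMatrix(n + 1, 3);
  }
  int last = n;
  for (int k = 0; k <= n; ++k) {
    double t = t0 + k * dt;
    double tot = x[0] + x[1] + x[2];
    if (k > 0 && k % meas_every == 0 && ISNA(breach)) {
      if (kind == 1) {                        // adaptive: on/off at thresholds
        if (phase_on && tot <= 0.5 * v0) { phase_on = false; cur = 0.0; }
        else if (!phase_on && tot >= v0) { phase_on = true; cur = 1.0; }
      } else if (kind == 2) {                 // titration: +/- one grid step
        if (tot > band_hi * v_target) d10 += step10;
        else if (tot < band_lo * v_target) d10 -= step10;
        if (d10 < 0) d10 = 0;
        if (d10 > 10) d10 = 10;
        cur = d10 / 10.0;
      }
    }
    if (keep_path) {
      tg[k] = t; dose[k] = cur;
      for (int i = 0; i < 3; ++i) X(k, i) = x[i];
    }
    if (ISNA(breach) && tot > p.cap) { breach = t; last = k; break; }
    if (k == n) { last = n; break; }
    rk4_step(p, x, dt, cur, cur, cur);
  }
  NumericVector xf(3);
  if (keep_path) {
    for (int i = 0; i < 3; ++i) xf[i] = X(last, i);
    tg = tg[Range(0, last)];
    dose = dose[Range(0, last)];
    X = X(Range(0, last), _);
  } else {
    for (int i = 0; i < 3; ++i) xf[i] = x[i];
  }
  List out = List::create(_["breach_time"] = breach, _["final_state"] = xf,
                          _["final_dose"] = cur, _["baseline_volume"] = v0);
  if (keep_path) {
    out["t"] = tg; out["x"] = X; out["dose"] = dose;
  }
  return out;
}

namespace {

// lambda-dot = -(2 (x - x*) + J^T costate), the adjoint of the running cost
// plus linearized dynamics.
inline void costate_rhs(const Pars& p, const double x[3], double lam,
                        const double cs[3], const double xstar[3],
                        bool finite_diff, double out[3]) {
  double J[3][3];
  if (finite_diff) jac_fd(p, x, lam, J); else jac(p, x, lam, J);
  for (int i = 0; i < 3; ++i) {
    double s = 2.0 * (x[i] - xstar[i]);
    for (int j = 0; j < 3; ++j) s += J[j][i] * cs[j];
    out[i] = -s;
  }
}

// Backward RK4 sweep over a stored state path (linear interpolation between
// nodes); terminal condition costate(tf) = 0.
void costate_sweep(const Pars& p, const NumericMatrix& X,
                   const NumericVector& u, const NumericVector& tg,
                   const double xstar[3], bool finite_diff, NumericMatrix& L) {
  int n = X.nrow() - 1;
  double cs[3] = {0.0, 0.0, 0.0};
  for (int i = 0; i < 3; ++i) L(n, i) = 0.0;
  for (int k = n - 1; k >= 0; --k) {
    double dt = tg[k + 1] - tg[k];
    double xk[3], xk1[3], xm[3];
    for (int i = 0; i < 3; ++i) {
      xk[i] = X(k, i); xk1[i] = X(k + 1, i); xm[i] = 0.5 * (xk[i] + xk1[i]);
    }
    double lm = 0.5 * (u[k] + u[k + 1]);
    double k1[3], k2[3], k3[3], k4[3], tmp[3];
    // integrating backward: step of -dt from t_{k+1} to t_k
    costate_rhs(p, xk1, u[k + 1], cs, xstar, finite_diff, k1);
    for (int i = 0; i < 3; ++i) tmp[i] = cs[i] - 0.5 * dt * k1[i];
    costate_rhs(p, xm, lm, tmp, xstar, finite_diff, k2);
    for (int i = 0; i < 3; ++i) tmp[i] = cs[i] - 0.5 * dt * k2[i];
    costate_rhs(p, xm, lm, tmp, xstar, finite_diff, k3);
    for (int i = 0; i < 3; ++i) tmp[i] = cs[i] - dt * k3[i];
    costate_rhs(p, xk, u[k], tmp, xstar, finite_diff, k4);
    for (int i = 0; i < 3; ++i) {
      cs[i] -= dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      L(k, i) = cs[i];
    }
  }
}

// Dose-dependent part of the Hamiltonian: only the T+ and TP drift terms
// depend on the dose, through mu(lam) and K_TP(lam).
//   h(lam) = -b / mu(lam) - d / K_TP(lam)
inline void ham_coefs(const Pars& p, const double x[3], const double cs[3],
                      double& b, double& d) {
  double m2 = x[1] > p.eps ? x[1] : p.eps;
  double S0 = p.A[0][0] * x[0] + p.A[0][1] * x[1] + p.A[0][2] * x[2];
  double S1 = p.A[1][0] * x[0] + p.A[1][1] * x[1] + p.A[1][2] * x[2];
  b = cs[0] * p.r[0] * x[0] * S0 / m2;
  d = cs[1] * p.r[1] * x[1] * S1;
}

double ham_u(const Pars& p, double b, double d, double lam) {
  return -b / mu_of(p, lam) - d / k2_of(p, lam);
}

// Grid search plus golden-section refinement of h over [0, 1].
double minimize_dose(const Pars& p, const double x[3], const double cs[3],
                     double prev, int ngrid) {
  double b, d;
  ham_coefs(p, x, cs, b, d);
  double best = 0.0, hbest = R_PosInf, hmin = R_PosInf, hmax = R_NegInf;
  for (int i = 0; i < ngrid; ++i) {
    double lam = (double)i / (ngrid - 1);
    double h = ham_u(p, b, d, lam);
    if (h < hbest) { hbest = h; best = lam; }
    if (h < hmin) hmin = h;
    if (h > hmax) hmax = h;
  }
  double scale = std::max(std::fabs(hmin), std::fabs(hmax));
  if (hmax - hmin <= 1e-14 * std::max(scale, 1.0))
    return ISNA(prev) ? 0.0 : prev;          // flat Hamiltonian: tie-break
  double step = 1.0 / (ngrid - 1);
  double lo = std::max(0.0, best - step), hi = std::min(1.0, best + step);
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double c = hi - gr * (hi - lo), e = lo + gr * (hi - lo);
  double fc = ham_u(p, b, d, c), fe = ham_u(p, b, d, e);
  for (int it = 0; it < 60 && hi - lo > 1e-10; ++it) {
    if (fc < fe) {
      hi = e; e = c; fe = fc;
      c = hi - gr * (hi - lo); fc = ham_u(p, b, d, c);
    } else {
      lo = c; c = e; fc = fe;
      e = lo + gr * (hi - lo); fe = ham_u(p, b, d, e);
    }
  }
  double mid = 0.5 * (lo + hi);
  return ham_u(p, b, d, mid) <= hbest ? mid : best;
}

void forward_sweep(const Pars& p, const double x0[3], const NumericVector& u,
                   double t0, double dt, NumericMatrix& X) {
  int n = X.nrow() - 1;
  double x[3] = {x0[0], x0[1], x0[2]};
  for (int i = 0; i < 3; ++i) X(0, i) = x[i];
  for (int k = 0; k < n; ++k) {
    double lm = 0.5 * (u[k] + u[k + 1]);
    rk4_step(p, x, dt, u[k], lm, u[k + 1]);
    for (int i = 0; i < 3; ++i) X(k + 1, i) = x[i];
  }
}

double objective_trapz(const NumericMatrix& X, const double xstar[3], double dt) {
  int n = X.nrow() - 1;
  double acc = 0.0, prevg = 0.0;
  for (int k = 0; k <= n; ++k) {
    double g = 0.0;
    for (int i = 0; i < 3; ++i) {
      double e = X(k, i) - xstar[i];
      g += e * e;
    }
    if (k > 0) acc += 0.5 * dt * (g + prevg);
    prevg = g;
  }
  return acc;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_costate_backward(NumericVector tg, NumericMatrix X,
                                   NumericVector u, NumericVector xstar,
                                   List params, bool finite_diff = false) {
  Pars p = unpack(params);
  double xs[3] = {xstar[0], xstar[1], xstar[2]};
  NumericMatrix L(X.nrow(), 3);
  costate_sweep(p, X, u, tg, xs, finite_diff, L);
  return L;
}

// [[Rcpp::export]]
double cpp_pointwise_dose(NumericVector x, NumericVector costate,
                          double prev, List params, int ngrid = 1001) {
  Pars p = unpack(params);
  double xx[3] = {x[0], x[1], x[2]}, cs[3] = {costate[0], costate[1], costate[2]};
  return minimize_dose(p, xx, cs, prev, ngrid);
}

// Forward-Backward Sweep: iterate forward state, backward costate, pointwise
// Hamiltonian minimization with relaxation omega, until the maximum absolute
// control change drops below tol.
// [[Rcpp::export]]
List cpp_fbs(NumericVector x0, NumericVector xstar, List params, double t0,
             double tf, double dt, double omega, double tol, int max_iter,
             NumericVector u_init, int ngrid = 1001) {
  Pars p = unpack(params);
  int n = (int)std::lround((tf - t0) / dt);
  NumericVector tg(n + 1), u(n + 1);
  for (int k = 0; k <= n; ++k) {
    tg[k] = t0 + k * dt;
    u[k] = u_init[u_init.size() == 1 ? 0 : k];
  }
  double xs[3] = {xstar[0], xstar[1], xstar[2]};
  double xx0[3] = {x0[0], x0[1], x0[2]};
  NumericMatrix X(n + 1, 3), L(n + 1, 3), Xtry(n + 1, 3);
  NumericVector umin(n + 1), utry(n + 1);
  std::vector<double> obj_hist;
  bool converged = false;
  int iters = 0, violations = 0;
  forward_sweep(p, xx0, u, t0, dt, X);
  double obj_cur = objective_trapz(X, xs, dt);
  obj_hist.push_back(obj_cur);
  for (int it = 1; it <= max_iter; ++it) {
    iters = it;
    costate_sweep(p, X, u, tg, xs, false, L);
    for (int k = 0; k <= n; ++k) {
      double xk[3] = {X(k, 0), X(k, 1), X(k, 2)};
      double csk[3] = {L(k, 0), L(k, 1), L(k, 2)};
      umin[k] = minimize_dose(p, xk, csk, u[k], ngrid);
    }
    // backtracking on the relaxation step: accept the largest step (up to
    // omega) whose objective does not increase beyond 0.1%
    double s = omega, obj_try = 0.0, delta = 0.0;
    bool accepted = false;
    for (int trial = 0; trial < 40; ++trial) {
      delta = 0.0;
      for (int k = 0; k <= n; ++k) {
        double v = (1.0 - s) * u[k] + s * umin[k];
        if (v < 0.0) v = 0.0;
        if (v > 1.0) v = 1.0;
        utry[k] = v;
        double ch = std::fabs(v - u[k]);
        if (ch > delta) delta = ch;
      }
      forward_sweep(p, xx0, utry, t0, dt, Xtry);
      obj_try = objective_trapz(Xtry, xs, dt);
      if (obj_try <= obj_cur * 1.001 + 1e-12) { accepted = true; break; }
      s *= 0.5;
    }
    if (!accepted) {          // no improving step: stationary for this sweep
      converged = true;
      break;
    }
    if (s < omega) ++violations;   // full relaxation step was rejected
    for (int k = 0; k <= n; ++k) u[k] = utry[k];
    for (int k = 0; k <= n; ++k)
      for (int i = 0; i < 3; ++i) X(k, i) = Xtry(k, i);
    obj_cur = obj_try;
    obj_hist.push_back(obj_cur);
    if (delta < tol) { converged = true; break; }
    Rcpp::checkUserInterrupt();
  }
  // final consistent forward/backward pass under the returned control
  forward_sweep(p, xx0, u, t0, dt, X);
  costate_sweep(p, X, u, tg, xs, false, L);
  double obj = objective_trapz(X, xs, dt);
  return List::create(_["t"] = tg, _["x"] = X, _["costate"] = L,
                      _["control"] = u, _["objective"] = obj,
                      _["iterations"] = iters, _["converged"] = converged,
                      _["objective_history"] = wrap(obj_hist),
                      _["step_rejections"] = violations);
}
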