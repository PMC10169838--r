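// Stiff integrator for the six-species adaptor/antibody/antigen binding
// network.  Fourth-order Kaps-Rentrop Rosenbrock method (Shampine's
// parameter set) with the analytic Jacobian of the mass-action right-hand
// side.  Rate constants may span many orders of magnitude, so an L-stable
// linearly implicit method is required; explicit steppers would need
// stability-limited steps of ~1/(kf*[Ab]) over a 1e6 s horizon.
//
// Species order: Tc, Ab, Tu, Tc.Ab, Ab.Tu, Tc.Ab.Tu   (concentrations, nM)
// Rate order:    kf1, kf2, kf3, kf4, kr1, kr2, kr3, kr4

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NSP = 6;

static inline void mass_action_rhs(const double* y, const double* k, double* f) {
  const double r1 = k[0] * y[0] * y[1];
  const double r2 = k[4] * y[3];
  const double r3 = k[1] * y[1] * y[2];
  const double r4 = k[5] * y[4];
  const double r5 = k[2] * y[3] * y[2];
  const double r6 = k[6] * y[5];
  const double r7 = k[3] * y[0] * y[4];
  const double r8 = k[7] * y[5];
  f[0] = -r1 + r2 - r7 + r8;
  f[1] = -r1 + r2 - r3 + r4;
  f[2] = -r3 + r4 - r5 + r6;
  f[3] =  r1 - r2 - r5 + r6;
  f[4] =  r3 - r4 - r7 + r8;
  f[5] =  r5 - r6 + r7 - r8;
}

static inline void mass_action_jac(const double* y, const double* k, double J[NSP][NSP]) {
  for (int i = 0; i < NSP; ++i)
    for (int j = 0; j < NSP; ++j) J[i][j] = 0.0;
  const double kf1 = k[0], kf2 = k[1], kf3 = k[2], kf4 = k[3];
  const double kr1 = k[4], kr2 = k[5], kr3 = k[6], kr4 = k[7];

  J[0][0] = -kf1 * y[1] - kf4 * y[4];
  J[0][1] = -kf1 * y[0];
  J[0][3] =  kr1;
  J[0][4] = -kf4 * y[0];
  J[0][5] =  kr4;

  J[1][0] = -kf1 * y[1];
  J[1][1] = -kf1 * y[0] - kf2 * y[2];
  J[1][2] = -kf2 * y[1];
  J[1][3] =  kr1;
  J[1][4] =  kr2;

  J[2][1] = -kf2 * y[2];
  J[2][2] = -kf2 * y[1] - kf3 * y[3];
  J[2][3] = -kf3 * y[2];
  J[2][4] =  kr2;
  J[2][5] =  kr3;

  J[3][0] =  kf1 * y[1];
  J[3][1] =  kf1 * y[0];
  J[3][2] = -kf3 * y[3];
  J[3][3] = -kr1 - kf3 * y[2];
  J[3][5] =  kr3;

  J[4][0] = -kf4 * y[4];
  J[4][1] =  kf2 * y[2];
  J[4][2] =  kf2 * y[1];
  J[4][4] = -kr2 - kf4 * y[0];
  J[4][5] =  kr4;

  J[5][0] =  kf4 * y[4];
  J[5][2] =  kf3 * y[3];
  J[5][3] =  kf3 * y[2];
  J[5][4] =  kf4 * y[0];
  J[5][5] = -kr3 - kr4;
}

// LU decomposition with partial pivoting, in place; returns false if singular.
static bool lu_decompose(double A[NSP][NSP], int piv[NSP]) {
  for (int i = 0; i < NSP; ++i) piv[i] = i;
  for (int c = 0; c < NSP; ++c) {
    int p = c;
    double amax = std::fabs(A[c][c]);
    for (int r = c + 1; r < NSP; ++r) {
      const double v = std::fabs(A[r][c]);
      if (v > amax) { amax = v; p = r; }
    }
    if (amax == 0.0) return false;
    if (p != c) {
      for (int j = 0; j < NSP; ++j) std::swap(A[c][j], A[p][j]);
      std::swap(piv[c], piv[p]);
    }
    const double inv = 1.0 / A[c][c];
    for (int r = c + 1; r < NSP; ++r) {
      const double m = A[r][c] * inv;
      A[r][c] = m;
      for (int j = c + 1; j < NSP; ++j) A[r][j] -= m * A[c][j];
    }
  }
  return true;
}

static void lu_solve(const double A[NSP][NSP], const int piv[NSP],
                     const double* b, double* x) {
  double t[NSP];
  for (int i = 0; i < NSP; ++i) t[i] = b[piv[i]];
  for (int i = 1; i < NSP; ++i)
    for (int j = 0; j < i; ++j) t[i] -= A[i][j] * t[j];
  for (int i = NSP - 1; i >= 0; --i) {
    for (int j = i + 1; j < NSP; ++j) t[i] -= A[i][j] * t[j];
    t[i] /= A[i][i];
  }
  for (int i = 0; i < NSP; ++i) x[i] = t[i];
}

// Kaps-Rentrop coefficients (Shampine's set, as used for GRK4 steppers).
static const double GAM = 0.5;
static const double A21 = 2.0;
static const double A31 = 48.0 / 25.0, A32 = 6.0 / 25.0;
static const double C21 = -8.0;
static const double C31 = 372.0 / 25.0, C32 = 12.0 / 5.0;
static const double C41 = -112.0 / 125.0, C42 = -54.0 / 125.0, C43 = -2.0 / 5.0;
static const double B1 = 19.0 / 9.0, B2 = 0.5, B3 = 25.0 / 108.0, B4 = 125.0 / 108.0;
static const double E1 = 17.0 / 54.0, E2 = 7.0 / 36.0, E3 = 0.0, E4 = 125.0 / 108.0;

// Advance y from t0 to t1.  h carries the trial step across calls so that
// successive output intervals reuse the adapted step size.
// Returns 0 on success, 1 if max_steps exhausted, 2 on irrecoverable step.
static int integrate_core(double* y, const double* k, double t0, double t1,
                          double rtol, double atol, int max_steps, double* h_io,
                          long* nstep_io) {
  double t = t0;
  double h = *h_io;
  const double span = t1 - t0;
  if (span <= 0.0) return 0;
  if (h <= 0.0 || h > span) h = std::min(span, std::max(span * 1e-6, 1e-6));

  double f1[NSP], f2[NSP], f3[NSP];
  double g1[NSP], g2[NSP], g3[NSP], g4[NSP];
  double rhs[NSP], ytmp[NSP], ynew[NSP], err[NSP];
  double A[NSP][NSP], J[NSP][NSP];
  int piv[NSP];

  int steps = 0;
  while (t < t1) {
    if (steps++ > max_steps) { *h_io = h; return 1; }
    if (t + h > t1) h = t1 - t;

    mass_action_rhs(y, k, f1);
    mass_action_jac(y, k, J);

    bool ok = false;
    double errmax = 0.0;
    // A = I/(gamma*h) - J
    const double d = 1.0 / (GAM * h);
    for (int i = 0; i < NSP; ++i) {
      for (int j = 0; j < NSP; ++j) A[i][j] = -J[i][j];
      A[i][i] += d;
    }
    if (lu_decompose(A, piv)) {
      lu_solve(A, piv, f1, g1);

      for (int i = 0; i < NSP; ++i) ytmp[i] = y[i] + A21 * g1[i];
      mass_action_rhs(ytmp, k, f2);
      for (int i = 0; i < NSP; ++i) rhs[i] = f2[i] + C21 * g1[i] / h;
      lu_solve(A, piv, rhs, g2);

      for (int i = 0; i < NSP; ++i) ytmp[i] = y[i] + A31 * g1[i] + A32 * g2[i];
      mass_action_rhs(ytmp, k, f3);
      for (int i = 0; i < NSP; ++i)
        rhs[i] = f3[i] + (C31 * g1[i] + C32 * g2[i]) / h;
      lu_solve(A, piv, rhs, g3);

      // stage 4 reuses f3 (Kaps-Rentrop: a43 = 0, same evaluation point)
      for (int i = 0; i < NSP; ++i)
        rhs[i] = f3[i] + (C41 * g1[i] + C42 * g2[i] + C43 * g3[i]) / h;
      lu_solve(A, piv, rhs, g4);

      ok = true;
      errmax = 0.0;
      for (int i = 0; i < NSP; ++i) {
        ynew[i] = y[i] + B1 * g1[i] + B2 * g2[i] + B3 * g3[i] + B4 * g4[i];
        err[i]  = E1 * g1[i] + E2 * g2[i] + E3 * g3[i] + E4 * g4[i];
        if (!std::isfinite(ynew[i])) { ok = false; break; }
        const double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
        const double e = std::fabs(err[i]) / sc;
        if (e > errmax) errmax = e;
      }
    }

    if (ok && errmax <= 1.0) {
      t += h;
      for (int i = 0; i < NSP; ++i) y[i] = ynew[i];
      double fac = 0.9 * std::pow(std::max(errmax, 1e-16), -0.25);
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = ok ? std::max(0.1, 0.9 * std::pow(errmax, -1.0 / 3.0)) : 0.5;
      h *= fac;
      // give up only when the step can no longer advance time
      if (h < span * 1e-16 || t + h == t) { *h_io = h; return 2; }
    }
    if (nstep_io) (*nstep_io)++;
  }
  *h_io = h;
  return 0;
}

//' @noRd
// [[Rcpp::export(name = ".ode_rhs_cpp")]]
NumericVector ode_rhs_cpp(NumericVector state, NumericVector rates) {
  double f[NSP];
  mass_action_rhs(REAL(state), REAL(rates), f);
  return NumericVector(f, f + NSP);
}

//' @noRd
// [[Rcpp::export(name = ".integrate_kinetics_cpp")]]
List integrate_kinetics_cpp(NumericVector y0, NumericVector rates,
                            NumericVector times, double rtol, double atol,
                            int max_steps) {
  const int nt = times.size();
  NumericMatrix out(nt, NSP);
  double y[NSP];
  for (int i = 0; i < NSP; ++i) y[i] = y0[i];
  for (int j = 0; j < NSP; ++j) out(0, j) = y[j];

  double h = -1.0;
  long nsteps = 0;
  int status = 0;
  int reached = nt;
  for (int ti = 1; ti < nt; ++ti) {
    status = integrate_core(y, REAL(rates), times[ti - 1], times[ti], rtol,
                            atol, max_steps, &h, &nsteps);
    if (status != 0) { reached = ti; break; }
    for (int j = 0; j < NSP; ++j) out(ti, j) = y[j];
  }
  return List::create(_["states"] = out, _["status"] = status,
                      _["n_steps"] = (double)nsteps,
                      _["n_times_completed"] = reached);
}

//' @noRd
// [[Rcpp::export(name = ".equilibrium_states_cpp")]]
List equilibrium_states_cpp(NumericVector ab0, double tc0, double tu0,
                            NumericVector rates, double t_max, double rtol,
                            double atol, int max_steps) {
  const int nd = ab0.size();
  NumericMatrix out(nd, NSP);
  IntegerVector status(nd);
  for (int di = 0; di < nd; ++di) {
    double y[NSP] = { tc0, ab0[di], tu0, 0.0, 0.0, 0.0 };
    int st = 0;
    if (ab0[di] > 0.0) {
      double h = -1.0;
      st = integrate_core(y, REAL(rates), 0.0, t_max, rtol, atol, max_steps,
                          &h, (long*)0);
    } else {
      y[1] = 0.0;  // no adaptor: nothing binds
    }
    status[di] = st;
    for (int j = 0; j < NSP; ++j) out(di, j) = y[j];
  }
  return List::create(_["states"] = out, _["status"] = status);
}
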