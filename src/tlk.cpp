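#include <Rcpp.h>
using namespace Rcpp;

// Two-lesion kinetic right-hand side:
//   dL1/dt = -l1*L1 - eta*L1*(L1+L2)
//   dL2/dt = -l2*L2 - eta*L2*(L1+L2)
//   dLL/dt = b1*l1*L1 + b2*l2*L2 + frac*eta*(L1+L2)^2
static inline void tlk_rhs_c(double L1, double L2,
                             double l1, double l2,
                             double b1, double b2, double eta, double frac,
                             double &d1, double &d2, double &dL) {
  const double tot = L1 + L2;
  d1 = -l1 * L1 - eta * L1 * tot;
  d2 = -l2 * L2 - eta * L2 * tot;
  dL = b1 * l1 * L1 + b2 * l2 * L2 + frac * eta * tot * tot;
}

static inline void rk4_step(double h, double &L1, double &L2, double &LL,
                            double l1, double l2,
                            double b1, double b2, double eta, double frac) {
  double k1a, k1b, k1c, k2a, k2b, k2c, k3a, k3b, k3c, k4a, k4b, k4c;
  tlk_rhs_c(L1, L2, l1, l2, b1, b2, eta, frac, k1a, k1b, k1c);
  tlk_rhs_c(L1 + 0.5 * h * k1a, L2 + 0.5 * h * k1b, l1, l2, b1, b2, eta, frac,
            k2a, k2b, k2c);
  tlk_rhs_c(L1 + 0.5 * h * k2a, L2 + 0.5 * h * k2b, l1, l2, b1, b2, eta, frac,
            k3a, k3b, k3c);
  tlk_rhs_c(L1 + h * k3a, L2 + h * k3b, l1, l2, b1, b2, eta, frac,
            k4a, k4b, k4c);
  L1 += h / 6.0 * (k1a + 2.0 * k2a + 2.0 * k3a + k4a);
  L2 += h / 6.0 * (k1b + 2.0 * k2b + 2.0 * k3b + k4b);
  LL += h / 6.0 * (k1c + 2.0 * k2c + 2.0 * k3c + k4c);
}

// Fixed-step RK4 over [0, T] for a batch of nuclei with per-nucleus repair
// rates. Returns final (L1, L2, L_lethal) per nucleus. Tiny negative
// round-off (> -1e-9) is clamped to zero; anything lower aborts, signalling
// that dt is too large for the rate constants.
// [[Rcpp::export]]
NumericMatrix tlk_integrate_batch(NumericVector L1_0, NumericVector L2_0,
                                  NumericVector lam1, NumericVector lam2,
                                  double beta1, double beta2, double eta,
                                  double lethal_pair_frac,
                                  double T, double dt) {
  const R_xlen_t n = L1_0.size();
  if (L2_0.size() != n || lam1.size() != n || lam2.size() != n)
    stop("initial states and rate vectors must have equal length");
  if (T <= 0.0 || dt <= 0.0 || dt > T) stop("need 0 < dt <= T");
  long nsteps = (long)std::llround(T / dt);
  if (nsteps < 1) nsteps = 1;
  const double h = T / (double)nsteps;
  NumericMatrix out(n, 3);
  for (R_xlen_t i = 0; i < n; ++i) {
    double L1 = L1_0[i], L2 = L2_0[i], LL = 0.0;
    const double l1 = lam1[i], l2 = lam2[i];
    if (L1 < 0.0 || L2 < 0.0) stop("negative initial lesion count for nucleus %d", (int)(i + 1));
    for (long s = 0; s < nsteps; ++s) {
      rk4_step(h, L1, L2, LL, l1, l2, beta1, beta2, eta, lethal_pair_frac);
      if (L1 < -1e-9 || L2 < -1e-9)
        stop("lesion count went below -1e-9 at t = %g h (nucleus %d): time step %g h is too large, reduce dt",
             (s + 1) * h, (int)(i + 1), h);
      if (L1 < 0.0) L1 = 0.0;
      if (L2 < 0.0) L2 = 0.0;
    }
    out(i, 0) = L1;
    out(i, 1) = L2;
    out(i, 2) = LL;
  }
  return out;
}

// Lethality integrals over [0, T] for a batch of nuclei:
//   I1 = integral lam1*L1 dt   (simple-DSB linear-repair throughput)
//   I2 = integral lam2*L2 dt   (complex-DSB linear-repair throughput)
//   J3 = integral (L1+L2)^2 dt (pairwise-interaction exposure)
// These do not depend on beta1/beta2, and
//   L_lethal(T) = beta1*I1 + beta2*I2 + lethal_pair_frac*eta*J3
// exactly (on the same RK4 grid), which makes the lethality fractions
// linear parameters of the model. Integrated with the same RK4 stages as
// the state itself.
// [[Rcpp::export]]
NumericMatrix tlk_lethality_integrals(NumericVector L1_0, NumericVector L2_0,
                                      NumericVector lam1, NumericVector lam2,
                                      double eta, double T, double dt) {
  const R_xlen_t n = L1_0.size();
  if (L2_0.size() != n || lam1.size() != n || lam2.size() != n)
    stop("initial states and rate vectors must have equal length");
  if (T <= 0.0 || dt <= 0.0 || dt > T) stop("need 0 < dt <= T");
  long nsteps = (long)std::llround(T / dt);
  if (nsteps < 1) nsteps = 1;
  const double h = T / (double)nsteps;
  NumericMatrix out(n, 3);
  for (R_xlen_t i = 0; i < n; ++i) {
    double L1 = L1_0[i], L2 = L2_0[i];
    double I1 = 0.0, I2 = 0.0, J3 = 0.0;
    const double l1 = lam1[i], l2 = lam2[i];
    if (L1 < 0.0 || L2 < 0.0) stop("negative initial lesion count for nucleus %d", (int)(i + 1));
    for (long s = 0; s < nsteps; ++s) {
      // RK4 on (L1, L2) with simultaneous quadrature of the integrands
      double d1, d2, dL;
      const double a1 = L1, a2 = L2;
      tlk_rhs_c(a1, a2, l1, l2, 0.0, 0.0, eta, 0.0, d1, d2, dL);
      const double b1s = a1 + 0.5 * h * d1, b2s = a2 + 0.5 * h * d2;
      double e1, e2;
      tlk_rhs_c(b1s, b2s, l1, l2, 0.0, 0.0, eta, 0.0, e1, e2, dL);
      const double c1s = a1 + 0.5 * h * e1, c2s = a2 + 0.5 * h * e2;
      double f1, f2;
      tlk_rhs_c(c1s, c2s, l1, l2, 0.0, 0.0, eta, 0.0, f1, f2, dL);
      const double g1s = a1 + h * f1, g2s = a2 + h * f2;
      double g1, g2;
      tlk_rhs_c(g1s, g2s, l1, l2, 0.0, 0.0, eta, 0.0, g1, g2, dL);
      I1 += h / 6.0 * l1 * (a1 + 2.0 * b1s + 2.0 * c1s + g1s);
      I2 += h / 6.0 * l2 * (a2 + 2.0 * b2s + 2.0 * c2s + g2s);
      const double sa = a1 + a2, sb = b1s + b2s, sc = c1s + c2s, sg = g1s + g2s;
      J3 += h / 6.0 * (sa * sa + 2.0 * sb * sb + 2.0 * sc * sc + sg * sg);
      L1 += h / 6.0 * (d1 + 2.0 * e1 + 2.0 * f1 + g1);
      L2 += h / 6.0 * (d2 + 2.0 * e2 + 2.0 * f2 + g2);
      if (L1 < -1e-9 || L2 < -1e-9)
        stop("lesion count went below -1e-9 at t = %g h (nucleus %d): reduce dt",
             (s + 1) * h, (int)(i + 1));
      if (L1 < 0.0) L1 = 0.0;
      if (L2 < 0.0) L2 = 0.0;
    }
    out(i, 0) = I1;
    out(i, 1) = I2;
    out(i, 2) = J3;
  }
  return out;
}

// Full trajectory for a single nucleus on the fixed RK4 grid.
// Returns (nsteps+1) x 4: time, L1, L2, L_lethal.
// [[Rcpp::export]]
NumericMatrix tlk_integrate_trajectory(double L1_0, double L2_0,
                                       double lam1, double lam2,
                                       double beta1, double beta2, double eta,
                                       double lethal_pair_frac,
                                       double T, double dt) {
  if (T <= 0.0 || dt <= 0.0 || dt > T) stop("need 0 < dt <= T");
  if (L1_0 < 0.0 || L2_0 < 0.0) stop("negative initial lesion count");
  long nsteps = (long)std::llround(T / dt);
  if (nsteps < 1) nsteps = 1;
  const double h = T / (double)nsteps;
  NumericMatrix out(nsteps + 1, 4);
  double L1 = L1_0, L2 = L2_0, LL = 0.0;
  out(0, 0) = 0.0; out(0, 1) = L1; out(0, 2) = L2; out(0, 3) = 0.0;
  for (long s = 0; s < nsteps; ++s) {
    rk4_step(h, L1, L2, LL, lam1, lam2, beta1, beta2, eta, lethal_pair_frac);
    if (L1 < -1e-9 || L2 < -1e-9)
      stop("lesion count went below -1e-9 at t = %g h: time step %g h is too large, reduce dt",
           (s + 1) * h, h);
    if (L1 < 0.0) L1 = 0.0;
    if (L2 < 0.0) L2 = 0.0;
    out(s + 1, 0) = (s + 1) * h;
    out(s + 1, 1) = L1;
    out(s + 1, 2) = L2;
    out(s + 1, 3) = LL;
  }
  return out;
}
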