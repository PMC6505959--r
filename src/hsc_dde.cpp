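// Fixed-step RK4 integrator for the six-compartment clonal hematopoiesis
// DDE system, with cubic Hermite dense output for the delayed-state lookup.
//
// State ordering everywhere: (H1, H2, M1, M2, L1, L2).
// Parameter vector ordering must match .pack_params() on the R side:
// (r1, r2, h1, h2, K_H, gamma, phi, delta_H0, delta_M0, delta_L0,
//  alpha_M, alpha_L, tau, K_M, K_L).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Pars {
  double r1, r2, h1, h2, KH, gamma, phi, dH0, dM0, dL0, aM, aL, tau, KM, KL;
};

static Pars unpack(const NumericVector& p) {
  Pars q;
  q.r1 = p[0];  q.r2 = p[1];  q.h1 = p[2];  q.h2 = p[3];  q.KH = p[4];
  q.gamma = p[5]; q.phi = p[6]; q.dH0 = p[7]; q.dM0 = p[8]; q.dL0 = p[9];
  q.aM = p[10]; q.aL = p[11]; q.tau = p[12]; q.KM = p[13]; q.KL = p[14];
  return q;
}

// Right-hand side of the model. Demand signals use the CURRENT myeloid and
// lymphoid totals; only the influx into the daughter compartments uses the
// delayed HSC state. delta is the niche-degradation increment added to all
// three baseline death rates.
static inline void rhs(const double* y, const double* ydel, const Pars& p,
                       double delta, double* f) {
  const double sigM = std::exp(-(y[2] + y[3]) / p.KM);
  const double sigL = std::exp(-(y[4] + y[5]) / p.KL);
  const double D = p.gamma * (p.phi * sigM + (1.0 - p.phi) * sigL);
  const double dH = p.dH0 + delta;
  const double dM = p.dM0 + delta;
  const double dL = p.dL0 + delta;
  f[0] = p.r1 * y[0] * (1.0 - (y[0] + p.h2 * y[1]) / p.KH) - D * y[0] - dH * y[0];
  f[1] = p.r2 * y[1] * (1.0 - (y[1] + p.h1 * y[0]) / p.KH) - D * y[1] - dH * y[1];
  f[2] = p.aM * p.phi * ydel[0] - dM * y[2];
  f[3] = p.aM * p.phi * ydel[1] - dM * y[3];
  f[4] = p.aL * (1.0 - p.phi) * ydel[0] - dL * y[4];
  f[5] = p.aL * (1.0 - p.phi) * ydel[1] - dL * y[5];
}

// Delayed full-state lookup at time td. Constant history for td <= 0;
// stored grid value at nodes; cubic Hermite between nodes (4th-order
// accurate locally, matching the RK4 global order).
static inline void lookup(double td, const NumericMatrix& Y,
                          const NumericMatrix& F, const double* hist,
                          double step, int filled, double* out) {
  if (td <= 0.0) {
    for (int j = 0; j < 6; ++j) out[j] = hist[j];
    return;
  }
  const double u = td / step;
  int k = (int)std::floor(u + 1e-9);
  if (k > filled - 1) k = filled - 1;
  double th = u - k;
  if (k >= filled) { k = filled; th = 0.0; }
  if (th < 1e-12) {
    for (int j = 0; j < 6; ++j) out[j] = Y(k, j);
    return;
  }
  const double th2 = th * th, th3 = th2 * th;
  const double h00 = 2.0 * th3 - 3.0 * th2 + 1.0;
  const double h10 = th3 - 2.0 * th2 + th;
  const double h01 = -2.0 * th3 + 3.0 * th2;
  const double h11 = th3 - th2;
  for (int j = 0; j < 6; ++j) {
    out[j] = h00 * Y(k, j) + h10 * step * F(k, j) +
             h01 * Y(k + 1, j) + h11 * step * F(k + 1, j);
  }
}

// [[Rcpp::export(name = ".hsc_rhs_cpp")]]
NumericVector hsc_rhs_cpp(NumericVector state, NumericVector delayed,
                          NumericVector par, double delta) {
  Pars p = unpack(par);
  NumericVector f(6);
  rhs(REAL(state), REAL(delayed), p, delta, REAL(f));
  return f;
}

// [[Rcpp::export(name = ".hsc_integrate_cpp")]]
List hsc_integrate_cpp(NumericVector par, NumericVector init,
                       NumericVector history, double delta,
                       double treatment_time, double t_end, double step) {
  const Pars p = unpack(par);
  const int n = (int)std::lround(t_end / step);
  const bool treat = R_finite(treatment_time);

  NumericMatrix Y(n + 1, 6), F(n + 1, 6);
  NumericVector tgrid(n + 1);
  const double* hist = REAL(history);
  double ydel[6], k1[6], k2[6], k3[6], k4[6], ytmp[6], fst[6];
  long clipped = 0;

  for (int j = 0; j < 6; ++j) Y(0, j) = init[j];
  tgrid[0] = 0.0;
  // Stored node derivative: the value used going forward from that node
  // (right limit across the treatment discontinuity).
  {
    const double d0 = (treat && 0.0 >= treatment_time) ? 0.0 : delta;
    double y0[6];
    for (int j = 0; j < 6; ++j) y0[j] = Y(0, j);
    lookup(-p.tau, Y, F, hist, step, 0, ydel);
    rhs(y0, ydel, p, d0, fst);
    for (int j = 0; j < 6; ++j) F(0, j) = fst[j];
  }

  for (int i = 0; i < n; ++i) {
    const double t = i * step;
    // Delta is constant within a step; the treatment instant must fall on a
    // node (validated on the R side), so no step straddles the jump.
    const double dnow = (treat && t >= treatment_time) ? 0.0 : delta;
    double y[6];
    for (int j = 0; j < 6; ++j) y[j] = Y(i, j);

    lookup(t - p.tau, Y, F, hist, step, i, ydel);
    rhs(y, ydel, p, dnow, k1);

    lookup(t + 0.5 * step - p.tau, Y, F, hist, step, i, ydel);
    for (int j = 0; j < 6; ++j) ytmp[j] = y[j] + 0.5 * step * k1[j];
    rhs(ytmp, ydel, p, dnow, k2);
    for (int j = 0; j < 6; ++j) ytmp[j] = y[j] + 0.5 * step * k2[j];
    rhs(ytmp, ydel, p, dnow, k3);

    lookup(t + step - p.tau, Y, F, hist, step, i, ydel);
    for (int j = 0; j < 6; ++j) ytmp[j] = y[j] + step * k3[j];
    rhs(ytmp, ydel, p, dnow, k4);

    for (int j = 0; j < 6; ++j) {
      double ynew = y[j] + step / 6.0 *
        (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (ynew < 0.0) {
        ynew = 0.0;  // population-level model: clip numerical undershoot
        ++clipped;
      }
      if (!R_finite(ynew))
        stop("non-finite state at t = %g (compartment %d)", t + step, j + 1);
      Y(i + 1, j) = ynew;
    }
    tgrid[i + 1] = (i + 1) * step;

    const double dnext = (treat && tgrid[i + 1] >= treatment_time) ? 0.0 : delta;
    for (int j = 0; j < 6; ++j) ytmp[j] = Y(i + 1, j);
    lookup(tgrid[i + 1] - p.tau, Y, F, hist, step, i + 1, ydel);
    rhs(ytmp, ydel, p, dnext, fst);
    for (int j = 0; j < 6; ++j) F(i + 1, j) = fst[j];
  }

  return List::create(_["time"] = tgrid, _["state"] = Y, _["deriv"] = F,
                      _["clipped"] = (double)clipped);
}
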