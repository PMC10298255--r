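#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Explicit finite-difference march for 1-D drying of a thin film.
//
// Nodes x = 0..Z on a uniform grid of spacing dl; x = 0 is the sealed
// (zero-flux) inner face, x = Z is the air-side face pinned at the
// equilibrium moisture Me. The effective diffusivity is evaluated at every
// node each step from the moisture/temperature law, the step size is taken
// from the scheme's stability bound (recomputed every step), and requested
// output times are filled by linear interpolation between the bracketing
// internal steps. Marching stops early once the normalized mean moisture
// ratio falls below stop_tol; remaining output rows repeat the final state.
//
// form: 0 = all-in-exponent law, 1 = additive law clamped at dfloor.
// geom: 0 planar, 1 cylindrical, 2 spherical (adds geom*D/r * dM/dx).
// bcoef: inner-node relaxation coefficient (6 = printed scheme, 2 = ghost);
//        also sets the stability bound dl^2/(bcoef*Dmax).
// dt_fixed > 0 overrides the adaptive step (caller must ensure stability).

static inline double node_deff(double M, double arr, double a, double b,
                               int form, double dfloor) {
  if (form == 0) {
    return arr * std::exp(a * M - b * M * M);
  }
  double d = arr + a * M - b * M * M;
  return d > dfloor ? d : dfloor;
}

// [[Rcpp::export(name = ".march_cpp")]]
List march_cpp(NumericVector init, double dl, double Tk, double Me,
               double D0, double Ea, double a, double b,
               int form, double dfloor, double geom, int bcoef,
               double safety, double stop_tol, double M0ref,
               NumericVector out_times, double dt_fixed,
               double max_steps) {
  const int Z = init.size() - 1;
  const int nt = out_times.size();
  const double Rgas = 8.3145;
  // Arrhenius part of the law; constant over the march (isothermal film)
  const double arr = D0 * std::exp(-Ea / (Rgas * Tk));
  std::vector<double> M(init.begin(), init.end());
  std::vector<double> Mp(Z + 1), D(Z + 1);
  NumericMatrix snap(nt, Z + 1);
  double t = 0.0, tprev = 0.0, dt = NA_REAL;
  double dt_min = R_PosInf, dt_max = 0.0;
  double steps = 0.0;
  bool ok = true, stopped = false;
  double t_stop = NA_REAL;
  int ti = 0;

  // snapshots exactly at t = 0 come straight from the initial state
  while (ti < nt && out_times[ti] <= 0.0) {
    for (int x = 0; x <= Z; ++x) snap(ti, x) = M[x];
    ++ti;
  }

  const double dl2 = dl * dl;
  while (ti < nt) {
    double Dmax = 0.0;
    for (int x = 0; x <= Z; ++x) {
      D[x] = node_deff(M[x], arr, a, b, form, dfloor);
      if (D[x] > Dmax) Dmax = D[x];
    }
    if (!(Dmax > 0.0) || !std::isfinite(Dmax)) { ok = false; break; }
    dt = (dt_fixed > 0.0) ? dt_fixed
                          : safety * dl2 / (static_cast<double>(bcoef) * Dmax);
    if (dt < dt_min) dt_min = dt;
    if (dt > dt_max) dt_max = dt;

    std::swap(M, Mp);
    // inner sealed face: relaxation toward the first interior node
    M[0] = Mp[0] + bcoef * D[0] * dt / dl2 * (Mp[1] - Mp[0]);
    // interior: conservative stencil D*Mxx + D'x*Mx (+ curvilinear term)
    for (int x = 1; x < Z; ++x) {
      double lap = (Mp[x + 1] - 2.0 * Mp[x] + Mp[x - 1]) / dl2;
      double gradD = (D[x + 1] - D[x - 1]) / (2.0 * dl);
      double gradM = (Mp[x + 1] - Mp[x - 1]) / (2.0 * dl);
      double upd = D[x] * lap + gradD * gradM;
      if (geom > 0.0) upd += geom * D[x] / (x * dl) * gradM;
      M[x] = Mp[x] + dt * upd;
    }
    M[Z] = Me;
    tprev = t;
    t += dt;
    steps += 1.0;

    while (ti < nt && out_times[ti] <= t) {
      double w = (out_times[ti] - tprev) / dt;
      for (int x = 0; x <= Z; ++x)
        snap(ti, x) = (1.0 - w) * Mp[x] + w * M[x];
      ++ti;
    }

    if (stop_tol > 0.0 && M0ref > Me) {
      double s = 0.5 * M[0] + 0.5 * M[Z];
      for (int x = 1; x < Z; ++x) s += M[x];
      double mavg = s / Z;
      if ((mavg - Me) / (M0ref - Me) < stop_tol) {
        stopped = true;
        t_stop = t;
        for (; ti < nt; ++ti)
          for (int x = 0; x <= Z; ++x) snap(ti, x) = M[x];
        break;
      }
    }
    if (steps >= max_steps) { ok = false; break; }
    bool fin = true;
    for (int x = 0; x <= Z; ++x)
      if (!std::isfinite(M[x])) { fin = false; break; }
    if (!fin) { ok = false; break; }
  }

  return List::create(
    _["snapshots"] = snap,
    _["ok"] = ok,
    _["steps"] = steps,
    _["dt_min"] = (steps > 0.0) ? dt_min : NA_REAL,
    _["dt_max"] = (steps > 0.0) ? dt_max : NA_REAL,
    _["early_stop"] = stopped,
    _["t_stop"] = t_stop,
    _["n_filled"] = ti);
}
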