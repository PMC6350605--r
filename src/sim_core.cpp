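// Fixed-step RK4 co-integrator for the digestion + glucose-insulin DDE model.
//
// One flat state vector per simulation:
//   y[0] G (mmol/l), y[1] I (pM),
//   y[2..5] stomach monosaccharide / lipid / protein / fiber (g),
//   y[6] intestinal free monosaccharide (g),
//   y[7] cumulative absorbed carbohydrate (g),
//   y[8] cumulative plasma insulin appearance (pmol/kgBW),
//   then 2 slots per starch portion (stomach mass, intestine mass, g),
//   then 2 slots per insulin administration (S1, S2, pmol/kgBW).
//
// Starch portions and depots for the whole window are allocated up front with
// zero mass and filled at their event times, so the ODE dimension is fixed.
// The pancreatic delay term uses a per-step history buffer of G with linear
// interpolation; requires tau_G >= step. Events (meals, injections, restarts)
// are applied at step boundaries; the R wrapper rounds event times to the grid.
//
// Note: the depot cascade adds the injected dose to S1 (u(t) > 0 increases
// depot mass); plasma appearance per depot is S2 / (V_I * t_max,I).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double MMOL_PER_G = 1000.0 / 180.16; // glucose molar mass

// [[Rcpp::export]]
List sim_core(NumericVector meal_time, NumericVector meal_mono,
              NumericVector meal_lipid, NumericVector meal_protein,
              NumericVector meal_fiber,
              NumericVector starch_time, NumericVector starch_mass,
              NumericVector starch_gi,
              NumericVector ins_time, NumericVector ins_s1,
              NumericVector ins_tmax,
              NumericVector restart_time, NumericVector restart_value,
              NumericVector out_times,
              NumericVector gly, double body_weight, NumericVector absp,
              double G0, double I0, double horizon, double step,
              NumericMatrix prof_tab, IntegerVector prof_param,
              double start_mod) {
  const int nm = meal_time.size(), np = starch_time.size(),
            nd = ins_time.size(), nr = restart_time.size(),
            nout = out_times.size(), nprof = prof_param.size();
  const int nstate = 9 + 2 * np + 2 * nd;
  const int nsteps = (int)std::lround(horizon / step);
  const double tau_base = gly[6];
  if (tau_base < step)
    stop("delay tau_G (%.3f min) must be >= integration step (%.3f min)",
         tau_base, step);

  std::vector<double> hist(nsteps + 1, G0);
  double preG = G0; // constant pre-history before t = 0 (or last restart seed)

  std::vector<double> y(nstate, 0.0);
  y[0] = G0; y[1] = I0;

  // event step indices (times are grid-aligned by the R wrapper)
  auto idx_of = [step](double t) { return (int)std::lround(t / step); };

  const double kge = absp[0], khyd = absp[1], kabs = absp[2],
               cl = absp[3], cp = absp[4], cf = absp[5];

  auto lag = [&](double td, int filled) -> double {
    if (td <= 0.0) return preG;
    double x = td / step;
    int i0 = (int)std::floor(x);
    if (i0 >= filled) return hist[filled];
    double w = x - i0;
    return hist[i0] * (1.0 - w) + hist[i0 + 1] * w;
  };

  std::vector<double> dy(nstate), k1(nstate), k2(nstate), k3(nstate),
      k4(nstate), tmp(nstate);

  int filled = 0; // highest valid index in hist

  auto deriv = [&](double t, const std::vector<double>& s,
                   std::vector<double>& d) {
    double pv[9];
    for (int k = 0; k < 9; ++k) pv[k] = gly[k];
    if (nprof > 0) {
      double x = start_mod + t;
      double mod = x - 1440.0 * std::floor(x / 1440.0);
      if (mod >= 1440.0) mod = 0.0;
      int j = (int)mod;
      double w = mod - j;
      for (int r = 0; r < nprof; ++r)
        pv[prof_param[r]] *=
            prof_tab(r, j) * (1.0 - w) + prof_tab(r, j + 1) * w;
    }
    const double kxgi = pv[0], tgh = pv[1], vg = pv[2], kxi = pv[3],
                 tig = pv[4], vi = pv[5], tau = pv[6], gstar = pv[7],
                 gam = pv[8];
    const double G = s[0], I = s[1];
    const double Ms = s[2], L = s[3], P = s[4], Fb = s[5], Q = s[6];

    // gastric emptying retarded by lipids, proteins and fibers in the stomach
    double retard = 1.0 + cl * std::max(L, 0.0) + cp * std::max(P, 0.0) +
                    cf * std::max(Fb, 0.0);
    double kemp = kge / retard;
    d[2] = -kemp * Ms;
    d[3] = -kemp * L;
    d[4] = -kemp * P;
    d[5] = -kemp * Fb;
    double hyd = 0.0;
    for (int p = 0; p < np; ++p) {
      double ss = s[9 + 2 * p], si = s[10 + 2 * p];
      double h = khyd * starch_gi[p] * si;
      d[9 + 2 * p] = -kemp * ss;
      d[10 + 2 * p] = kemp * ss - h;
      hyd += h;
    }
    d[6] = kemp * Ms + hyd - kabs * Q;
    d[7] = kabs * Q;
    double da = kabs * Q * MMOL_PER_G / (vg * body_weight);

    double Gd = lag(t - tau, filled);
    double f = 0.0;
    if (Gd > 0.0) {
      double r = std::pow(Gd / gstar, gam);
      f = r / (1.0 + r);
    }
    double dep = 0.0, app = 0.0;
    int off = 9 + 2 * np;
    for (int q = 0; q < nd; ++q) {
      double s1 = s[off + 2 * q], s2 = s[off + 2 * q + 1];
      double tm = ins_tmax[q];
      d[off + 2 * q] = -s1 / tm;
      d[off + 2 * q + 1] = (s1 - s2) / tm;
      dep += s2 / (vi * tm);
      app += s2 / tm;
    }
    d[0] = -kxgi * G * I + tgh / vg + da;
    d[1] = -kxi * I + (tig / vi) * f + dep;
    d[8] = app;
  };

  NumericVector Gout(nout, NA_REAL), Iout(nout, NA_REAL);
  std::vector<int> out_idx(nout);
  for (int k = 0; k < nout; ++k) out_idx[k] = idx_of(out_times[k]);

  int im = 0, ip = 0, iq = 0, ir = 0, io = 0;
  bool ok = true;

  for (int i = 0; i <= nsteps; ++i) {
    double t = i * step;

    // record model output (prediction before any event at this instant)
    while (io < nout && out_idx[io] == i) {
      Gout[io] = y[0];
      Iout[io] = y[1];
      ++io;
    }

    // restarts: set G to the measurement, re-seed history, keep I and depots
    while (ir < nr && idx_of(restart_time[ir]) == i) {
      double v = restart_value[ir];
      y[0] = v;
      int j0 = idx_of(std::max(0.0, t - tau_base));
      for (int j = j0; j <= i && j <= nsteps; ++j) hist[j] = v;
      if (t - tau_base < 0) preG = v;
      ++ir;
    }
    // meals: impulse into the stomach compartments
    while (im < nm && idx_of(meal_time[im]) == i) {
      y[2] += meal_mono[im];
      y[3] += meal_lipid[im];
      y[4] += meal_protein[im];
      y[5] += meal_fiber[im];
      ++im;
    }
    while (ip < np && idx_of(starch_time[ip]) == i) {
      y[9 + 2 * ip] += starch_mass[ip];
      ++ip;
    }
    // injections: dose enters the first subcutaneous depot
    while (iq < nd && idx_of(ins_time[iq]) == i) {
      y[9 + 2 * np + 2 * iq] += ins_s1[iq];
      ++iq;
    }

    hist[i] = y[0];
    filled = i;
    if (i == nsteps) break;

    deriv(t, y, k1);
    for (int j = 0; j < nstate; ++j) tmp[j] = y[j] + 0.5 * step * k1[j];
    deriv(t + 0.5 * step, tmp, k2);
    for (int j = 0; j < nstate; ++j) tmp[j] = y[j] + 0.5 * step * k2[j];
    deriv(t + 0.5 * step, tmp, k3);
    for (int j = 0; j < nstate; ++j) tmp[j] = y[j] + step * k3[j];
    deriv(t + step, tmp, k4);
    for (int j = 0; j < nstate; ++j)
      y[j] += step / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);

    // clamp integrator-noise negatives on mass-like states
    for (int j = 1; j < nstate; ++j)
      if (y[j] < 0.0 && y[j] > -1e-9) y[j] = 0.0;

    if (!std::isfinite(y[0]) || !std::isfinite(y[1]) || y[0] <= 0.0 ||
        y[0] > 1000.0 || y[1] > 1e9) {
      ok = false;
      break;
    }
  }

  double stom_dig = y[2], intes_dig = y[6];
  for (int p = 0; p < np; ++p) {
    stom_dig += y[9 + 2 * p];
    intes_dig += y[10 + 2 * p];
  }
  double dep_res = 0.0;
  for (int q = 0; q < nd; ++q)
    dep_res += y[9 + 2 * np + 2 * q] + y[9 + 2 * np + 2 * q + 1];

  return List::create(
      _["ok"] = ok, _["G"] = Gout, _["I"] = Iout,
      _["final_G"] = y[0], _["final_I"] = y[1],
      _["stomach_digestible_g"] = stom_dig,
      _["intestine_digestible_g"] = intes_dig,
      _["cum_absorbed_g"] = y[7],
      _["depot_residual_pmol_kg"] = dep_res,
      _["cum_insulin_appearance_pmol_kg"] = y[8]);
}
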