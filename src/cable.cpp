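// Staggered backward-Euler solver (Hines scheme) for the modified
// Hodgkin-Huxley propagating action potential on a finite cable.
//
// Voltage is advanced implicitly (tridiagonal solve, Thomas algorithm);
// gates are advanced on staggered half steps with the exact exponential
// update of the linear gate ODE.  Membrane capacitance is time-varying:
// C_m = C0 + Cg_max * (G_Na / G_Na_ref) * (1 - m), treated quasi-statically
// as a coefficient on dV/dt, refreshed from m each step.
//
// Rate functions (with their Q10 factor) are tabulated on a fine voltage
// grid and linearly interpolated, which removes per-node exp() calls from
// the inner loop; the gate-update coefficients x_inf and exp(-dt*(a+b))
// are tabulated directly.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const double TAB_VMIN = -150.0;
const double TAB_VMAX = 100.0;
const double TAB_DV = 0.05;

// x/(1 - exp(-x/k)) with its removable singularity at x = 0
inline double vtrap(double x, double k) {
  if (std::fabs(x / k) < 1e-7) return k * (1.0 + x / (2.0 * k));
  return x / (1.0 - std::exp(-x / k));
}

struct RateSet {
  double an, bn, am, bm, ah, bh;
};

inline RateSet raw_rates(double v, double q10) {
  RateSet r;
  r.an = 0.01 * vtrap(v + 55.0, 10.0) * q10;
  r.bn = 0.125 * std::exp(-(v + 65.0) / 19.7) * q10;
  r.am = 0.1 * vtrap(v + 40.0, 10.0) * q10;
  r.bm = 4.0 * std::exp(-(v + 65.0) / 18.0) * q10;
  r.ah = 0.07 * std::exp(-(v + 65.0) / 20.0) * q10;
  r.bh = 1.8 / (1.0 + std::exp(-(v + 16.0) / 10.0)) * q10;
  return r;
}

struct GateTables {
  int n;
  std::vector<double> ninf, nexp, minf, mexp, hinf, hexp;
  void build(double tc, double dt) {
    double q10 = std::pow(3.0, (tc - 6.3) / 10.0);
    n = static_cast<int>(std::floor((TAB_VMAX - TAB_VMIN) / TAB_DV)) + 1;
    ninf.resize(n); nexp.resize(n); minf.resize(n);
    mexp.resize(n); hinf.resize(n); hexp.resize(n);
    for (int i = 0; i < n; ++i) {
      double v = TAB_VMIN + i * TAB_DV;
      RateSet r = raw_rates(v, q10);
      ninf[i] = r.an / (r.an + r.bn);
      nexp[i] = std::exp(-dt * (r.an + r.bn));
      minf[i] = r.am / (r.am + r.bm);
      mexp[i] = std::exp(-dt * (r.am + r.bm));
      hinf[i] = r.ah / (r.ah + r.bh);
      hexp[i] = std::exp(-dt * (r.ah + r.bh));
    }
  }
};

} // namespace

// Six rate constants (1/ms) at membrane potential v (mV), temperature tc (C).
// Exposed so the R-level rate functions and the solver share one definition.
// [[Rcpp::export(name = ".cpp_rate_constants")]]
NumericMatrix cpp_rate_constants(NumericVector v, double tc) {
  double q10 = std::pow(3.0, (tc - 6.3) / 10.0);
  int n = v.size();
  NumericMatrix out(n, 6);
  for (int i = 0; i < n; ++i) {
    RateSet r = raw_rates(v[i], q10);
    out(i, 0) = r.an; out(i, 1) = r.bn;
    out(i, 2) = r.am; out(i, 3) = r.bm;
    out(i, 4) = r.ah; out(i, 5) = r.bh;
  }
  colnames(out) = CharacterVector::create("alpha_n", "beta_n", "alpha_m",
                                          "beta_m", "alpha_h", "beta_h");
  return out;
}

// Advance the cable.  Compartment centres sit at x_i = (i - 1/2) dx; sealed
// (zero axial flux) ends.  The stimulus enters compartment 1 as a current
// density stim_amp / (2 pi r dx) for stim_dur ms.  record_idx are 1-based
// compartment indices whose V (and gates) are stored every step.
// stop_idx > 0 requests early termination once V at that compartment
// crosses 0 mV upward (used by threshold searches).
// [[Rcpp::export(name = ".cpp_cable_solve")]]
List cpp_cable_solve(double L, double r, double Ra, double GL,
                     double ENa, double EK, double C0, double Cg_max,
                     double GNa_ref, double tc, double dt, double dx,
                     double g_na, double g_k, double v_leak,
                     double stim_amp, double stim_dur, double t_total,
                     IntegerVector record_idx, int stop_idx,
                     double v_init) {
  const int nx = static_cast<int>(std::lround(L / dx));
  if (std::fabs(nx * dx - L) > 1e-9 * L)
    stop("dx must divide the cable length L");
  const int nsteps = static_cast<int>(std::lround(t_total / dt));
  const int nrec = record_idx.size();

  GateTables tab;
  tab.build(tc, dt);
  const double inv_dv = 1.0 / TAB_DV;
  const int tmax = tab.n - 2;

  // initial state: uniform v_init with gates at steady state
  double q10 = std::pow(3.0, (tc - 6.3) / 10.0);
  RateSet r0 = raw_rates(v_init, q10);
  std::vector<double> V(nx, v_init);
  std::vector<double> gn(nx, r0.an / (r0.an + r0.bn));
  std::vector<double> gm(nx, r0.am / (r0.am + r0.bm));
  std::vector<double> gh(nx, r0.ah / (r0.ah + r0.bh));

  const double ga = r / (2.0 * Ra);          // mS (per cm of length scale)
  const double ax = ga / (dx * dx);          // axial coupling, mS/cm^2
  const double stim_density = stim_amp / (2.0 * M_PI * r * dx); // uA/cm^2
  const int stim_steps = static_cast<int>(std::lround(stim_dur / dt));
  const double cg_scale = Cg_max * (g_na / GNa_ref);

  NumericMatrix recV(nsteps + 1, nrec), recM(nsteps + 1, nrec),
      recH(nsteps + 1, nrec), recN(nsteps + 1, nrec);
  for (int j = 0; j < nrec; ++j) {
    int idx = record_idx[j] - 1;
    if (idx < 0 || idx >= nx) stop("record index out of range");
    recV(0, j) = V[idx];
    recM(0, j) = gm[idx];
    recH(0, j) = gh[idx];
    recN(0, j) = gn[idx];
  }
  int stop0 = stop_idx - 1;
  bool stopped = false;
  int steps_done = nsteps;

  std::vector<double> diag(nx), rhs(nx), cp(nx), dp(nx);

  for (int s = 1; s <= nsteps; ++s) {
    // gates: t - dt/2 -> t + dt/2 using V(t)
    for (int i = 0; i < nx; ++i) {
      double u = (V[i] - TAB_VMIN) * inv_dv;
      int k = static_cast<int>(u);
      if (k < 0) { k = 0; u = 0.0; }
      else if (k > tmax) { k = tmax; u = static_cast<double>(tmax); }
      double w = u - k;
      double ni = tab.ninf[k] + w * (tab.ninf[k + 1] - tab.ninf[k]);
      double ne = tab.nexp[k] + w * (tab.nexp[k + 1] - tab.nexp[k]);
      double mi = tab.minf[k] + w * (tab.minf[k + 1] - tab.minf[k]);
      double me = tab.mexp[k] + w * (tab.mexp[k + 1] - tab.mexp[k]);
      double hi = tab.hinf[k] + w * (tab.hinf[k + 1] - tab.hinf[k]);
      double he = tab.hexp[k] + w * (tab.hexp[k + 1] - tab.hexp[k]);
      gn[i] = ni + (gn[i] - ni) * ne;
      gm[i] = mi + (gm[i] - mi) * me;
      gh[i] = hi + (gh[i] - hi) * he;
    }

    // implicit voltage step
    for (int i = 0; i < nx; ++i) {
      double n2 = gn[i] * gn[i];
      double gk4 = g_k * n2 * n2;
      double gna3 = g_na * gm[i] * gm[i] * gm[i] * gh[i];
      double cm = C0 + cg_scale * (1.0 - gm[i]);
      double cdt = cm / dt;
      double nb = (nx == 1) ? 0.0 : (i == 0 || i == nx - 1) ? 1.0 : 2.0;
      diag[i] = cdt + gk4 + gna3 + GL + nb * ax;
      rhs[i] = cdt * V[i] + gk4 * EK + gna3 * ENa + GL * v_leak;
    }
    if (s <= stim_steps) rhs[0] += stim_density;

    // Thomas algorithm; off-diagonals are the constant -ax
    cp[0] = -ax / diag[0];
    dp[0] = rhs[0] / diag[0];
    for (int i = 1; i < nx; ++i) {
      double denom = diag[i] + ax * cp[i - 1];
      cp[i] = -ax / denom;
      dp[i] = (rhs[i] + ax * dp[i - 1]) / denom;
    }
    V[nx - 1] = dp[nx - 1];
    for (int i = nx - 2; i >= 0; --i) V[i] = dp[i] - cp[i] * V[i + 1];

    if (!std::isfinite(V[0]) || !std::isfinite(V[nx / 2]))
      stop("numerical instability: non-finite voltage at step %d (t = %g ms)",
           s, s * dt);

    for (int j = 0; j < nrec; ++j) {
      int idx = record_idx[j] - 1;
      recV(s, j) = V[idx];
      recM(s, j) = gm[idx];
      recH(s, j) = gh[idx];
      recN(s, j) = gn[idx];
    }
    if (stop0 >= 0 && V[stop0] >= 0.0) {
      stopped = true;
      steps_done = s;
      break;
    }
    if ((s & 1023) == 0) {
      for (int i = 0; i < nx; ++i)
        if (!std::isfinite(V[i]))
          stop("numerical instability: non-finite voltage at step %d", s);
      Rcpp::checkUserInterrupt();
    }
  }

  if (steps_done < nsteps) {
    recV = recV(Range(0, steps_done), _);
    recM = recM(Range(0, steps_done), _);
    recH = recH(Range(0, steps_done), _);
    recN = recN(Range(0, steps_done), _);
  }
  NumericVector tvec(steps_done + 1);
  for (int s = 0; s <= steps_done; ++s) tvec[s] = s * dt;

  return List::create(
      _["time"] = tvec, _["v"] = recV, _["m"] = recM, _["h"] = recH,
      _["n"] = recN, _["v_final"] = NumericVector(V.begin(), V.end()),
      _["n_final"] = NumericVector(gn.begin(), gn.end()),
      _["m_final"] = NumericVector(gm.begin(), gm.end()),
      _["h_final"] = NumericVector(gh.begin(), gh.end()),
      _["stopped_early"] = stopped, _["steps_done"] = steps_done);
}
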