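// Explicit finite-difference monodomain solver on a 2D isotropic grid with
// spatially varying diffusion, no-flux boundaries, adaptive time stepping
// and coupled-but-inexcitable fibrotic nodes.
//
// dV/dt = div(D grad V) - (I_ion + I_stim)/Cm   (non-fibrotic nodes)
// dV/dt = div(D grad V)                         (fibrotic nodes)
//
// The flux-conservative 5-point stencil uses arithmetic-mean face
// diffusivities; boundary faces carry zero flux.  CRN kinetics use
// voltage-indexed lookup tables (steady states and Rush-Larsen relaxation
// factors per time step) so large grids stay tractable; the tables are
// checked against the direct formulation in the test suite.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include "crn.h"

using namespace Rcpp;

namespace {

const double TAB_VMIN = -150.0;
const double TAB_VMAX = 100.0;
const double TAB_DV = 0.02;
const int TAB_N = static_cast<int>((TAB_VMAX - TAB_VMIN) / TAB_DV) + 1;

// the 12 gates whose rates depend on V only (state indices)
const int VGATES[12] = {crn::IM, crn::IH, crn::IJ, crn::IOA, crn::IOI,
                        crn::IUA, crn::IUI, crn::IXR, crn::IXS,
                        crn::ID, crn::IF, crn::IW};

struct Tables {
  // per V-gate: steady state and time constant
  std::vector<double> inf[12], tau[12];
  // current helper factors of V
  std::vector<double> hK1, hKr, hgKur, hfNaK, hexpA, hexpB;
  // Rush-Larsen factors a = 1 - exp(-dt/tau), cached per dt
  std::map<long long, std::vector<std::vector<double> > > rl_cache;
  double ENa, EK, inak_fac, naca_fac;

  Tables() {
    for (int g = 0; g < 12; ++g) { inf[g].resize(TAB_N); tau[g].resize(TAB_N); }
    hK1.resize(TAB_N); hKr.resize(TAB_N); hgKur.resize(TAB_N);
    hfNaK.resize(TAB_N); hexpA.resize(TAB_N); hexpB.resize(TAB_N);
    crn::Deriv d;
    const double sigma = (std::exp(crn::Nao / 67.3) - 1.0) / 7.0;
    for (int i = 0; i < TAB_N; ++i) {
      double V = TAB_VMIN + i * TAB_DV;
      crn::voltage_rates(V, &d);
      for (int g = 0; g < 12; ++g) {
        inf[g][i] = d.inf[VGATES[g] - crn::GATE0];
        tau[g][i] = d.tau[VGATES[g] - crn::GATE0];
      }
      hK1[i] = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));
      hKr[i] = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));
      hgKur[i] = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
      hfNaK[i] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * crn::FRT * V) +
                        0.0365 * sigma * std::exp(-crn::FRT * V));
      hexpA[i] = std::exp(crn::gama * crn::FRT * V);
      hexpB[i] = std::exp((crn::gama - 1.0) * crn::FRT * V);
    }
    ENa = crn::E_Na();
    EK = crn::E_K();
    inak_fac = crn::Cm * crn::INaK_max *
        (1.0 / (1.0 + std::pow(crn::KmNai / crn::Nai_fixed, 1.5))) *
        (crn::Ko / (crn::Ko + crn::KmKo));
    naca_fac = crn::Cm * crn::INaCa_max /
        ((crn::KmNa * crn::KmNa * crn::KmNa + crn::Nao * crn::Nao * crn::Nao) *
         (crn::KmCa + crn::Cao));
  }

  const std::vector<std::vector<double> >& rl_for(double dt) {
    long long key = static_cast<long long>(dt * 1e9 + 0.5);
    std::map<long long, std::vector<std::vector<double> > >::iterator it =
        rl_cache.find(key);
    if (it != rl_cache.end()) return it->second;
    std::vector<std::vector<double> > a(12, std::vector<double>(TAB_N));
    for (int g = 0; g < 12; ++g)
      for (int i = 0; i < TAB_N; ++i)
        a[g][i] = 1.0 - std::exp(-dt / tau[g][i]);
    if (rl_cache.size() > 32) rl_cache.clear();
    return rl_cache.insert(std::make_pair(key, a)).first->second;
  }
};

Tables& tables() {
  static Tables tab;
  return tab;
}

inline double lerp(const std::vector<double>& t, int i, double w) {
  return t[i] + w * (t[i + 1] - t[i]);
}

// table-driven reaction update of one non-fibrotic node; returns I_ion (pA).
// g points at the 18 non-voltage states of the node (order IM..ICAREL).
inline double react_node(double V, double* g, const crn::Scales& sc,
                         const Tables& tab,
                         const std::vector<std::vector<double> >& rl,
                         double a_fca, double a_u, double dt) {
  double x = (V - TAB_VMIN) / TAB_DV;
  int i = static_cast<int>(x);
  if (i < 0) i = 0;
  if (i > TAB_N - 2) i = TAB_N - 2;
  double w = x - i;

  const double Cai = g[crn::ICAI - 1], Caup = g[crn::ICAUP - 1],
               Carel = g[crn::ICAREL - 1];
  const double m = g[crn::IM - 1], h = g[crn::IH - 1], j = g[crn::IJ - 1];
  const double oa = g[crn::IOA - 1], oi = g[crn::IOI - 1];
  const double ua = g[crn::IUA - 1], ui = g[crn::IUI - 1];
  const double xr = g[crn::IXR - 1], xs = g[crn::IXS - 1];
  const double d = g[crn::ID - 1], f = g[crn::IF - 1], fca = g[crn::IFCA - 1];
  const double u = g[crn::IU - 1], vg = g[crn::IVG - 1], wg = g[crn::IW - 1];

  const double ECa = 0.5 * crn::RTF * std::log(crn::Cao / Cai);
  const double iNa = crn::Cm * crn::gNa * m * m * m * h * j * (V - tab.ENa);
  const double iK1 = crn::Cm * sc.gK1 * crn::gK1 * (V - tab.EK) * lerp(tab.hK1, i, w);
  const double ito = crn::Cm * sc.gto * crn::gto * oa * oa * oa * oi * (V - tab.EK);
  const double iKur = crn::Cm * sc.gKur * lerp(tab.hgKur, i, w) * ua * ua * ua * ui * (V - tab.EK);
  const double iKr = crn::Cm * crn::gKr * xr * (V - tab.EK) * lerp(tab.hKr, i, w);
  const double iKs = crn::Cm * crn::gKs * xs * xs * (V - tab.EK);
  const double iCaL = crn::Cm * sc.gCaL * crn::gCaL * d * f * fca * (V - 65.0);
  const double iNaK = tab.inak_fac * lerp(tab.hfNaK, i, w);
  const double iNaCa = tab.naca_fac *
      (lerp(tab.hexpA, i, w) * crn::Nai_fixed * crn::Nai_fixed * crn::Nai_fixed * crn::Cao -
       lerp(tab.hexpB, i, w) * crn::Nao * crn::Nao * crn::Nao * Cai) /
      (1.0 + crn::ksat * lerp(tab.hexpB, i, w));
  const double ibNa = crn::Cm * crn::gbNa * (V - tab.ENa);
  const double ibCa = crn::Cm * crn::gbCa * (V - ECa);
  const double ipCa = crn::Cm * crn::IpCa_max * Cai / (0.0005 + Cai);

  const double Iion = iNa + iK1 + ito + iKur + iKr + iKs + iCaL + ipCa + iNaK +
                      iNaCa + ibNa + ibCa;

  // SR fluxes and Ca-dependent gates
  const double irel = crn::Krel * u * u * vg * wg * (Carel - Cai);
  const double itr = (Caup - Carel) / crn::tau_tr;
  const double iup = crn::Iup_max / (1.0 + crn::Kup / Cai);
  const double iupleak = crn::Iup_max * Caup / crn::Caup_max;
  const double Fn = 1e3 * (1e-15 * crn::Vrel * irel -
                           (1e-15 / (2.0 * crn::Frdy)) * (0.5 * iCaL - 0.2 * iNaCa));
  const double sigm1 = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  const double u_inf = sigm1;
  const double v_inf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  const double tau_v = 1.91 + 2.09 * sigm1;
  const double fca_inf = 1.0 / (1.0 + Cai / 0.00035);

  const double B1 = (2.0 * iNaCa - (ipCa + iCaL + ibCa)) / (2.0 * crn::Vi * crn::Frdy) +
                    (crn::Vup * (iupleak - iup) + irel * crn::Vrel) / crn::Vi;
  const double B2 = 1.0 +
      crn::TRPN_max * crn::Km_TRPN / ((Cai + crn::Km_TRPN) * (Cai + crn::Km_TRPN)) +
      crn::CMDN_max * crn::Km_CMDN / ((Cai + crn::Km_CMDN) * (Cai + crn::Km_CMDN));

  // gate updates (Rush-Larsen)
  for (int k = 0; k < 12; ++k) {
    int gi = VGATES[k] - 1;
    g[gi] += (lerp(tables().inf[k], i, w) - g[gi]) * lerp(rl[k], i, w);
  }
  g[crn::IFCA - 1] += (fca_inf - g[crn::IFCA - 1]) * a_fca;
  g[crn::IU - 1] += (u_inf - g[crn::IU - 1]) * a_u;
  g[crn::IVG - 1] += (v_inf - g[crn::IVG - 1]) * (1.0 - std::exp(-dt / tau_v));

  // concentration updates (forward Euler)
  g[crn::ICAI - 1] += dt * B1 / B2;
  g[crn::ICAUP - 1] += dt * (iup - (iupleak + itr * crn::Vrel / crn::Vup));
  g[crn::ICAREL - 1] += dt * (itr - irel) /
      (1.0 + crn::CSQN_max * crn::Km_CSQN /
                 ((Carel + crn::Km_CSQN) * (Carel + crn::Km_CSQN)));

  return Iion;
}

} // namespace

// [[Rcpp::export]]
List cpp_tissue_run(NumericMatrix D, LogicalMatrix fibrotic, double dx,
                    NumericMatrix init_state, NumericVector scales,
                    NumericVector stim_onset, NumericVector stim_duration,
                    NumericVector stim_amplitude, IntegerVector stim_nodes,
                    double duration, double frame_interval,
                    IntegerVector probe_nodes, double v_threshold,
                    int max_crossings, double dt_fine, double dt_max,
                    double dvdt_trigger, bool record_frames,
                    double probe_interval) {
  const int ny = D.nrow(), nx = D.ncol();
  const int N = nx * ny;
  if (fibrotic.nrow() != ny || fibrotic.ncol() != nx)
    stop("fibrotic mask dimensions must match D");
  if (init_state.nrow() != crn::NSTATE)
    stop("init_state must have %d rows", crn::NSTATE);
  if (init_state.ncol() != 1 && init_state.ncol() != N)
    stop("init_state must have 1 or nx*ny columns");
  crn::Scales sc;
  sc.gto = scales[0]; sc.gCaL = scales[1]; sc.gKur = scales[2]; sc.gK1 = scales[3];
  const int n_events = stim_onset.size();

  // state: V separated for the diffusion stencil; other 18 states node-major
  std::vector<double> V(N), G(static_cast<size_t>(N) * 18);
  for (int n = 0; n < N; ++n) {
    int col = (init_state.ncol() == 1) ? 0 : n;
    V[n] = init_state(crn::IV, col);
    for (int k = 0; k < 18; ++k) G[static_cast<size_t>(n) * 18 + k] = init_state(k + 1, col);
  }

  // face diffusivities (arithmetic mean), zero at boundaries
  double Dmax = 0.0;
  std::vector<double> wE(N, 0.0), wW(N, 0.0), wN(N, 0.0), wS(N, 0.0);
  const double inv_dx2 = 1.0 / (dx * dx);
  for (int jx = 0; jx < nx; ++jx) {
    for (int iy = 0; iy < ny; ++iy) {
      int n = iy + ny * jx;
      double d0 = D(iy, jx);
      if (d0 > Dmax) Dmax = d0;
      if (jx + 1 < nx) wE[n] = 0.5 * (d0 + D(iy, jx + 1)) * inv_dx2;
      if (jx > 0) wW[n] = 0.5 * (d0 + D(iy, jx - 1)) * inv_dx2;
      if (iy + 1 < ny) wN[n] = 0.5 * (d0 + D(iy + 1, jx)) * inv_dx2;
      if (iy > 0) wS[n] = 0.5 * (d0 + D(iy - 1, jx)) * inv_dx2;
    }
  }
  const double dt_stab = dx * dx / (4.0 * Dmax);
  const double dt_coarse = std::min(dt_max, dt_stab);
  if (dt_fine > dt_stab + 1e-12)
    stop("fine time step %f ms violates stability bound %f ms", dt_fine, dt_stab);

  std::vector<char> fib(N);
  for (int jx = 0; jx < nx; ++jx)
    for (int iy = 0; iy < ny; ++iy) fib[iy + ny * jx] = fibrotic(iy, jx) ? 1 : 0;
  std::vector<char> stim_mask(N, 0);
  for (int k = 0; k < stim_nodes.size(); ++k) {
    int n = stim_nodes[k];
    if (n < 0 || n >= N) stop("stimulus node index out of range");
    stim_mask[n] = 1;
  }

  Tables& tab = tables();

  // crossing records
  NumericMatrix t_up(max_crossings, N), t_down(max_crossings, N);
  std::fill(t_up.begin(), t_up.end(), NA_REAL);
  std::fill(t_down.begin(), t_down.end(), NA_REAL);
  IntegerVector n_up(N), n_down(N);

  // probes
  const int P = probe_nodes.size();
  std::vector<double> probe_t;
  std::vector<double> probe_v;
  double next_probe = 0.0;

  // frames
  int n_frames = record_frames ? static_cast<int>(duration / frame_interval) + 1 : 0;
  NumericMatrix frames(record_frames ? N : 0, n_frames);
  int frame_idx = 0;
  double next_frame = 0.0;

  std::vector<double> lap(N);
  double t = 0.0;
  double max_dvdt = 0.0;
  int n_steps = 0;

  while (t < duration - 1e-9) {
    // sample probes / frames scheduled at or before t
    if (P > 0 && t >= next_probe - 1e-9) {
      probe_t.push_back(t);
      for (int p = 0; p < P; ++p) probe_v.push_back(V[probe_nodes[p]]);
      next_probe += probe_interval;
    }
    if (record_frames && frame_idx < n_frames && t >= next_frame - 1e-9) {
      for (int n = 0; n < N; ++n) frames(n, frame_idx) = V[n];
      ++frame_idx;
      next_frame += frame_interval;
    }

    // stimulus amplitude now (events share one region and do not overlap)
    bool stim_active = false;
    double amp_now = 0.0;
    double next_edge = duration;
    for (int e = 0; e < n_events; ++e) {
      double on = stim_onset[e], off = stim_onset[e] + stim_duration[e];
      if (t >= on - 1e-9 && t < off - 1e-9) {
        stim_active = true;
        amp_now = stim_amplitude[e];
        if (off < next_edge) next_edge = off;
      } else if (on > t + 1e-9 && on < next_edge) {
        next_edge = on;
      }
    }
    if (P > 0 && next_probe < next_edge) next_edge = next_probe;
    if (record_frames && frame_idx < n_frames && next_frame < next_edge)
      next_edge = next_frame;

    double dt = (stim_active || max_dvdt > dvdt_trigger) ? dt_fine : dt_coarse;
    if (t + dt > next_edge + 1e-12) dt = next_edge - t;
    if (dt <= 1e-12) { t = next_edge; continue; }

    // diffusion term from current V
    for (int n = 0; n < N; ++n) {
      double v0 = V[n];
      double acc = 0.0;
      if (wE[n] != 0.0) acc += wE[n] * (V[n + ny] - v0);
      if (wW[n] != 0.0) acc += wW[n] * (V[n - ny] - v0);
      if (wN[n] != 0.0) acc += wN[n] * (V[n + 1] - v0);
      if (wS[n] != 0.0) acc += wS[n] * (V[n - 1] - v0);
      lap[n] = acc;
    }

    const std::vector<std::vector<double> >& rl = tab.rl_for(dt);
    const double a_fca = 1.0 - std::exp(-dt / crn::tau_fca);
    const double a_u = 1.0 - std::exp(-dt / crn::tau_u);

    double step_max = 0.0;
    for (int n = 0; n < N; ++n) {
      double dv = lap[n];
      if (!fib[n]) {
        double Iion = react_node(V[n], &G[static_cast<size_t>(n) * 18], sc, tab,
                                 rl, a_fca, a_u, dt);
        double istim = (stim_active && stim_mask[n]) ? amp_now : 0.0;
        dv -= (Iion + istim) / crn::Cm;
      }
      double v_new = V[n] + dt * dv;
      double adv = std::fabs(dv);
      if (adv > step_max) step_max = adv;
      // threshold crossing detection with linear interpolation
      if (V[n] < v_threshold) {
        if (v_new >= v_threshold && n_up[n] < max_crossings)
          t_up(n_up[n]++, n) = t + dt * (v_threshold - V[n]) / (v_new - V[n]);
      } else if (v_new < v_threshold && n_down[n] < max_crossings) {
        t_down(n_down[n]++, n) = t + dt * (v_threshold - V[n]) / (v_new - V[n]);
      }
      V[n] = v_new;
    }
    if (!std::isfinite(step_max)) {
      for (int n = 0; n < N; ++n)
        if (!std::isfinite(V[n]))
          stop("non-finite voltage at node %d (row %d, col %d) at t = %f ms",
               n + 1, n % ny + 1, n / ny + 1, t);
    }
    max_dvdt = step_max;
    t += dt;
    ++n_steps;
    if (n_steps % 2000 == 0) checkUserInterrupt();
  }

  // final scheduled samples at t = duration
  if (P > 0 && t >= next_probe - 1e-9) {
    probe_t.push_back(t);
    for (int p = 0; p < P; ++p) probe_v.push_back(V[probe_nodes[p]]);
  }
  if (record_frames && frame_idx < n_frames) {
    for (int n = 0; n < N; ++n) frames(n, frame_idx) = V[n];
    ++frame_idx;
  }

  NumericMatrix probes(P > 0 ? static_cast<int>(probe_t.size()) : 0, P);
  for (size_t r = 0; r < probe_t.size(); ++r)
    for (int p = 0; p < P; ++p) probes(r, p) = probe_v[r * P + p];

  NumericMatrix final_state(crn::NSTATE, N);
  for (int n = 0; n < N; ++n) {
    final_state(0, n) = V[n];
    for (int k = 0; k < 18; ++k) final_state(k + 1, n) = G[static_cast<size_t>(n) * 18 + k];
  }

  return List::create(
      _["t_up"] = t_up, _["t_down"] = t_down, _["n_up"] = n_up,
      _["n_down"] = n_down,
      _["probe_t"] = NumericVector(probe_t.begin(), probe_t.end()),
      _["probe_V"] = probes, _["frames"] = frames, _["n_frames"] = frame_idx,
      _["final_state"] = final_state, _["n_steps"] = n_steps,
      _["dt_coarse"] = dt_coarse, _["dt_stability"] = dt_stab);
}

// Pure diffusion update (I_ion and stimulus identically zero) for numerical
// conservation checks: n_steps explicit steps of size dt from V0.
// [[Rcpp::export]]
NumericMatrix cpp_diffuse_only(NumericMatrix D, double dx, NumericMatrix V0,
                               double dt, int n_steps) {
  const int ny = D.nrow(), nx = D.ncol();
  const int N = nx * ny;
  std::vector<double> V(V0.begin(), V0.end()), lap(N);
  std::vector<double> wE(N, 0.0), wW(N, 0.0), wN(N, 0.0), wS(N, 0.0);
  const double inv_dx2 = 1.0 / (dx * dx);
  for (int jx = 0; jx < nx; ++jx)
    for (int iy = 0; iy < ny; ++iy) {
      int n = iy + ny * jx;
      double d0 = D(iy, jx);
      if (jx + 1 < nx) wE[n] = 0.5 * (d0 + D(iy, jx + 1)) * inv_dx2;
      if (jx > 0) wW[n] = 0.5 * (d0 + D(iy, jx - 1)) * inv_dx2;
      if (iy + 1 < ny) wN[n] = 0.5 * (d0 + D(iy + 1, jx)) * inv_dx2;
      if (iy > 0) wS[n] = 0.5 * (d0 + D(iy - 1, jx)) * inv_dx2;
    }
  for (int s = 0; s < n_steps; ++s) {
    for (int n = 0; n < N; ++n) {
      double v0 = V[n];
      double acc = 0.0;
      if (wE[n] != 0.0) acc += wE[n] * (V[n + ny] - v0);
      if (wW[n] != 0.0) acc += wW[n] * (V[n - ny] - v0);
      if (wN[n] != 0.0) acc += wN[n] * (V[n + 1] - v0);
      if (wS[n] != 0.0) acc += wS[n] * (V[n - 1] - v0);
      lap[n] = acc;
    }
    for (int n = 0; n < N; ++n) V[n] += dt * lap[n];
  }
  NumericMatrix out(ny, nx);
  std::copy(V.begin(), V.end(), out.begin());
  return out;
}
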