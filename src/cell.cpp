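// Single-cell interface to the CRN model: stepping, pacing with adaptive
// time steps, and state/rate inspection.
#include <Rcpp.h>
#include <vector>
#include "crn.h"

using namespace Rcpp;

static crn::Scales as_scales(const NumericVector& sc) {
  if (sc.size() != 4) stop("scales must have 4 elements (gto, gCaL, gKur, gK1)");
  crn::Scales s;
  s.gto = sc[0]; s.gCaL = sc[1]; s.gKur = sc[2]; s.gK1 = sc[3];
  return s;
}

static const char* STATE_NAMES[crn::NSTATE] = {
  "V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
  "d", "f", "fCa", "u", "v", "w", "Ca_i", "Ca_up", "Ca_rel"
};

static void check_finite(const double* s, double t) {
  for (int k = 0; k < crn::NSTATE; ++k) {
    if (!std::isfinite(s[k]))
      stop("non-finite state component '%s' at t = %f ms", STATE_NAMES[k], t);
  }
}

// [[Rcpp::export]]
NumericVector cpp_crn_initial_state() {
  NumericVector out(crn::NSTATE);
  crn::initial_state(REAL(out));
  out.attr("names") = CharacterVector(STATE_NAMES, STATE_NAMES + crn::NSTATE);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_crn_step(NumericVector state, NumericVector scales,
                           double dt, double istim) {
  if (state.size() != crn::NSTATE) stop("state must have %d elements", crn::NSTATE);
  crn::Scales sc = as_scales(scales);
  NumericVector out = clone(state);
  if (dt > 0) crn::step(REAL(out), sc, dt, istim);
  check_finite(REAL(out), dt);
  out.attr("names") = CharacterVector(STATE_NAMES, STATE_NAMES + crn::NSTATE);
  return out;
}

// Gate steady states / time constants, concentration derivatives and total
// ionic current at a state (for rate-level checks).
// [[Rcpp::export]]
List cpp_crn_eval(NumericVector state, NumericVector scales) {
  if (state.size() != crn::NSTATE) stop("state must have %d elements", crn::NSTATE);
  crn::Scales sc = as_scales(scales);
  crn::Deriv d;
  crn::eval(REAL(state), sc, &d);
  NumericVector inf(d.inf, d.inf + crn::NGATE), tau(d.tau, d.tau + crn::NGATE);
  CharacterVector gn(STATE_NAMES + crn::GATE0, STATE_NAMES + crn::GATE0 + crn::NGATE);
  inf.attr("names") = gn;
  tau.attr("names") = gn;
  return List::create(_["inf"] = inf, _["tau"] = tau,
                      _["dCa_i"] = d.dCai, _["dCa_up"] = d.dCaup,
                      _["dCa_rel"] = d.dCarel, _["I_ion"] = d.Iion);
}

// Pace an isolated cell for n_beats at cycle length cl, with a stimulus
// pulse at the start of each beat.  Adaptive dt: fine while the stimulus is
// on or |dV/dt| from the previous step exceeds dvdt_trigger, else coarse.
// Optionally record the full state at fixed intervals during the final
// record_beats beats.
// [[Rcpp::export]]
List cpp_crn_pace(NumericVector state, NumericVector scales,
                  double cl, int n_beats,
                  double stim_amplitude, double stim_duration,
                  double dt_fine, double dt_coarse, double dvdt_trigger,
                  double record_interval, int record_beats) {
  if (state.size() != crn::NSTATE) stop("state must have %d elements", crn::NSTATE);
  if (cl <= stim_duration) stop("cycle length must exceed stimulus duration");
  crn::Scales sc = as_scales(scales);
  std::vector<double> s(REAL(state), REAL(state) + crn::NSTATE);

  std::vector<double> rec_t;
  std::vector<double> rec_s;
  LogicalVector excited(n_beats);

  double dvdt_prev = 0.0;
  for (int beat = 0; beat < n_beats; ++beat) {
    double t = 0.0;        // time within beat
    double t0 = beat * cl; // absolute time
    bool record = record_beats > 0 && beat >= n_beats - record_beats;
    double next_rec = 0.0;
    double vmax = -1e30;
    while (t < cl - 1e-9) {
      if (record && t >= next_rec - 1e-9) {
        rec_t.push_back(t0 + t);
        rec_s.insert(rec_s.end(), s.begin(), s.end());
        next_rec += record_interval;
      }
      bool stim_on = t < stim_duration - 1e-9;
      double dt = (stim_on || std::fabs(dvdt_prev) > dvdt_trigger) ? dt_fine
                                                                   : dt_coarse;
      double limit = cl;
      if (stim_on) limit = std::min(limit, stim_duration);
      if (record) limit = std::min(limit, next_rec);
      if (t + dt > limit) dt = limit - t;
      double v0 = s[crn::IV];
      crn::step(s.data(), sc, dt, stim_on ? stim_amplitude : 0.0);
      dvdt_prev = (s[crn::IV] - v0) / dt;
      t += dt;
      if (s[crn::IV] > vmax) vmax = s[crn::IV];
      if (!std::isfinite(s[crn::IV])) check_finite(s.data(), t0 + t);
    }
    check_finite(s.data(), t0 + t);
    excited[beat] = vmax > -40.0;
  }

  NumericVector out(s.begin(), s.end());
  out.attr("names") = CharacterVector(STATE_NAMES, STATE_NAMES + crn::NSTATE);
  int nrec = rec_t.size();
  NumericMatrix states(crn::NSTATE, nrec);
  for (int r = 0; r < nrec; ++r)
    for (int k = 0; k < crn::NSTATE; ++k) states(k, r) = rec_s[r * crn::NSTATE + k];
  states.attr("dimnames") = List::create(
      CharacterVector(STATE_NAMES, STATE_NAMES + crn::NSTATE), R_NilValue);
  return List::create(_["state"] = out,
                      _["t"] = NumericVector(rec_t.begin(), rec_t.end()),
                      _["states"] = states, _["excited"] = excited);
}
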