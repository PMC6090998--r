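#' CRN cell model parameters for a study variant
#'
#' Builds the parameter set of the Courtemanche-Ramirez-Nattel (CRN) human
#' atrial cell model for one of the two study variants. The `"normal"` variant
#' uses the published maximum conductances. The `"remodelled"` variant
#' represents electrical remodelling in persistent atrial fibrillation:
#' the maximum conductances of the transient outward current (Ito) and the
#' L-type calcium current (ICaL) are reduced by 65% (scale 0.35), the
#' ultrarapid delayed rectifier (IKur) by 49% (scale 0.51), and the inward
#' rectifier (IK1) is increased by 110% (scale 2.10). Only maximum
#' conductances are scaled; kinetics are unchanged.
#'
#' Intracellular sodium and potassium are clamped at their default initial
#' values (11.17 and 139.00 mM) in both variants to avoid slow drift.
#'
#' @param variant `"normal"` or `"remodelled"`.
#' @return An object of class `crn_parameters`: a list with fields
#'   `variant`, `scale_gto`, `scale_gCaL`, `scale_gKur`, `scale_gK1`,
#'   `Na_i_fixed` (mM), `K_i_fixed` (mM) and `Cm` (pF).
#' @export
#' @examples
#' p <- cell_parameters("remodelled")
#' p$scale_gK1
cell_parameters <- function(variant = c("normal", "remodelled")) {
  variant <- match.arg(variant)
  scales <- if (variant == "normal") c(1, 1, 1, 1) else c(0.35, 0.35, 0.51, 2.10)
  structure(
    list(
      variant = variant,
      scale_gto = scales[1],
      scale_gCaL = scales[2],
      scale_gKur = scales[3],
      scale_gK1 = scales[4],
      Na_i_fixed = 11.17,
      K_i_fixed = 139.00,
      Cm = 100
    ),
    class = "crn_parameters"
  )
}

#' @export
print.crn_parameters <- function(x, ...) {
  cat("CRN cell model parameters, variant:", x$variant, "\n")
  cat(sprintf("  conductance scales: gto %.2f, gCaL %.2f, gKur %.2f, gK1 %.2f\n",
              x$scale_gto, x$scale_gCaL, x$scale_gKur, x$scale_gK1))
  cat(sprintf("  clamped [Na+]i = %.2f mM, [K+]i = %.2f mM, Cm = %g pF\n",
              x$Na_i_fixed, x$K_i_fixed, x$Cm))
  invisible(x)
}

param_scales <- function(params) {
  stopifnot(inherits(params, "crn_parameters"))
  c(params$scale_gto, params$scale_gCaL, params$scale_gKur, params$scale_gK1)
}

#' Published resting state of the CRN model
#'
#' @return Named numeric vector with membrane voltage `V` (mV), the 15
#'   gating variables and the three calcium compartment concentrations (mM).
#' @export
crn_initial_state <- function() {
  cpp_crn_initial_state()
}

validate_cell_state <- function(state) {
  stopifnot(is.numeric(state), length(state) == 19)
  if (any(!is.finite(state))) {
    bad <- names(state)[!is.finite(state)][1]
    stop("non-finite state component '", bad, "'")
  }
  invisible(state)
}

#' Advance a single cell by one time step
#'
#' One integration step of an isolated CRN cell: gating variables advance by
#' the Rush-Larsen exponential scheme (exact relaxation towards the steady
#' state for rates frozen at the current voltage); membrane voltage and
#' calcium concentrations advance by forward Euler.
#'
#' @param state Named state vector as returned by [crn_initial_state()].
#' @param params A [cell_parameters()] object.
#' @param dt Time step, ms; must lie in `[0, 0.1]`. A zero step returns the
#'   state unchanged.
#' @param I_stim Stimulus current in pA; negative values are depolarizing
#'   (`dV/dt = -(I_ion + I_stim)/Cm`).
#' @return The updated state vector.
#' @export
step_cell <- function(state, params, dt, I_stim = 0) {
  validate_cell_state(state)
  stopifnot(dt >= 0, dt <= 0.1)
  cpp_crn_step(state, param_scales(params), dt, I_stim)
}

#' Pace a single cell and record its trajectory
#'
#' Paces an isolated cell at a fixed cycle length with the standard stimulus
#' (a -2000 pA, 2 ms current pulse at the start of each beat), using the same
#' adaptive time-step policy as the tissue solver (fine step while the
#' stimulus is on or |dV/dt| exceeds 5 mV/ms, coarse step otherwise).
#'
#' @param params A [cell_parameters()] object.
#' @param cycle_length Pacing cycle length, ms.
#' @param n_beats Number of beats.
#' @param state Starting state; defaults to the published resting state.
#' @param record_beats Number of final beats for which the full state is
#'   recorded at `record_interval` spacing (0 records nothing).
#' @param record_interval Sampling interval for recording, ms.
#' @param stim_amplitude,stim_duration Stimulus current (pA) and pulse
#'   duration (ms).
#' @param dt_fine,dt_coarse Adaptive time-step bounds, ms.
#' @return A list with `state` (final state), `t`, `states` (19 x n matrix of
#'   recorded states) and `excited` (logical per beat: did V cross -40 mV).
#' @export
pace_cell <- function(params, cycle_length = 1000, n_beats = 1,
                      state = crn_initial_state(),
                      record_beats = 0, record_interval = 1,
                      stim_amplitude = -2000, stim_duration = 2,
                      dt_fine = 0.01, dt_coarse = 0.1) {
  validate_cell_state(state)
  cpp_crn_pace(state, param_scales(params), cycle_length, as.integer(n_beats),
               stim_amplitude, stim_duration, dt_fine, dt_coarse, 5,
               record_interval, as.integer(record_beats))
}

.variant_cache <- new.env(parent = emptyenv())

#' Steady paced state of a cell variant
#'
#' Returns the state of a cell at the end of the 40th diastolic interval when
#' paced at a cycle length of 1,000 ms, starting from the published resting
#' state. This is the initial condition used for every tissue simulation.
#' The result is cached per variant, and is deterministic.
#'
#' @param params A [cell_parameters()] object.
#' @param n_beats Number of conditioning beats.
#' @param cycle_length Conditioning cycle length, ms.
#' @return A cell state vector.
#' @export
initialize_variant <- function(params, n_beats = 40, cycle_length = 1000) {
  key <- sprintf("%s_%d_%g", params$variant, n_beats, cycle_length)
  if (!is.null(.variant_cache[[key]])) return(.variant_cache[[key]])
  res <- pace_cell(params, cycle_length = cycle_length, n_beats = n_beats)
  if (!all(res$excited)) {
    stop("pacing failed to excite the cell on beat ",
         which(!res$excited)[1], "; the model is mis-specified")
  }
  .variant_cache[[key]] <- res$state
  res$state
}

#' Single-cell action potential duration
#'
#' APD measured on a steady-state paced beat as the time between the upward
#' and the next downward crossing of a fixed voltage threshold. The default
#' threshold of -73.0 mV corresponds approximately to 90% repolarization in
#' the CRN model and matches the tissue-level maps.
#'
#' @param params A [cell_parameters()] object.
#' @param cycle_length Pacing cycle length, ms.
#' @param threshold Crossing threshold, mV.
#' @return APD in ms.
#' @export
#' @examples
#' \donttest{
#' single_cell_apd(cell_parameters("normal"))
#' }
single_cell_apd <- function(params, cycle_length = 1000, threshold = -73) {
  state <- initialize_variant(params)
  res <- pace_cell(params, cycle_length = cycle_length, n_beats = 1,
                   state = state, record_beats = 1, record_interval = 0.1)
  v <- res$states["V", ]
  if (max(v) < threshold) stop("cell not excited: V never crossed ", threshold, " mV")
  cr <- detect_crossings(res$t, v, threshold = threshold)
  if (nrow(cr) < 1 || is.na(cr$t_down[1])) stop("cell not excited")
  cr$t_down[1] - cr$t_up[1]
}
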