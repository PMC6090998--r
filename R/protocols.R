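new_protocol <- function(kind, events, region, geometry, spiral_params = NULL) {
  if (nrow(events) > 1 && any(diff(events$onset) <= 0)) {
    stop("stimulus onsets must be strictly increasing")
  }
  structure(list(kind = kind, events = events, region = as.integer(region),
                 geometry = geometry, spiral_params = spiral_params),
            class = "pacing_protocol")
}

#' @export
print.pacing_protocol <- function(x, ...) {
  cat(sprintf("pacing_protocol '%s': %d stimuli on %d nodes\n", x$kind,
              nrow(x$events), length(x$region)))
  if (nrow(x$events) > 0) {
    cat("  onsets (ms):", paste(x$events$onset, collapse = ", "), "\n")
    cat(sprintf("  amplitude %g pA, duration %g ms\n", x$events$amplitude[1],
                x$events$duration[1]))
  }
  invisible(x)
}

# nodes of the 2.5 x 2.5 mm square block in the lower-left corner
corner_region <- function(geometry, size_mm = 2.5) {
  nb <- max(1L, round(size_mm / geometry$dx))
  as.integer(outer(seq_len(nb), (seq_len(nb) - 1L) * geometry$ny, `+`))
}

#' Corner pacing at arbitrary onsets
#'
#' Stimuli on the 2.5 x 2.5 mm lower-left corner block at the given onset
#' times — the building block of [build_s1s2()], also useful on its own for
#' single-beat activation mapping.
#'
#' @param geometry A [tissue_geometry()].
#' @param onsets Stimulus onset times, ms (strictly increasing).
#' @param amplitude Stimulus current, pA.
#' @param duration Pulse width, ms.
#' @return A `pacing_protocol`.
#' @export
corner_stimulus_protocol <- function(geometry, onsets, amplitude = -2000,
                                     duration = 2) {
  new_protocol("s1",
               data.frame(onset = onsets, duration = duration,
                          amplitude = amplitude),
               corner_region(geometry), geometry)
}

#' S1S2 pacing protocol
#'
#' Three regular (S1) stimuli at a cycle length of 1,000 ms followed by one
#' premature (S2) stimulus at a coupling interval of 400 ms, i.e. onsets at
#' 0, 1,000, 2,000 and 2,400 ms. Each stimulus injects -2000 pA for 2 ms
#' into the 2.5 x 2.5 mm square region in the lower-left corner. (A 1 ms
#' pulse of this amplitude injects only 2 pC — a 20 mV displacement of a
#' 100 pF membrane — which does not reach the sodium-current threshold of
#' the CRN model; 2 ms matches the original CRN stimulus charge and
#' reliably captures.)
#'
#' @param geometry A [tissue_geometry()].
#' @return A `pacing_protocol`.
#' @export
#' @examples
#' build_s1s2(tissue_geometry(100, 100))$events$onset
build_s1s2 <- function(geometry) {
  p <- corner_stimulus_protocol(geometry, onsets = c(0, 1000, 2000, 2400))
  p$kind <- "s1s2"
  p
}

#' Decremental pacing protocol
#'
#' Ten stimuli (-2000 pA, 2 ms; see [build_s1s2()] on the pulse width)
#' delivered to a central circular region of
#' radius 6.25 mm, with the inter-stimulus interval starting at 450 ms for
#' the normal variant (300 ms for the remodelled variant) and decreasing by
#' 25 ms per stimulus down to a final interval of 250 ms (150 ms
#' remodelled). For the remodelled variant the final interval is reached
#' after six decrements, and the remaining intervals stay clamped at 150 ms
#' so that ten stimuli are always delivered.
#'
#' @param variant Cell variant (name or [cell_parameters()]).
#' @param geometry A [tissue_geometry()].
#' @return A `pacing_protocol`.
#' @export
#' @examples
#' build_decremental("normal", tissue_geometry(100, 100))$events$onset
build_decremental <- function(variant, geometry) {
  params <- as_variant_params(variant)
  bounds <- if (params$variant == "normal") c(450, 250) else c(300, 150)
  intervals <- pmax(seq(bounds[1], by = -25, length.out = 9), bounds[2])
  onsets <- cumsum(c(0, intervals))
  # central disc, radius 6.25 mm
  cx <- geometry$nx * geometry$dx / 2
  cy <- geometry$ny * geometry$dx / 2
  xs <- (seq_len(geometry$nx) - 0.5) * geometry$dx
  ys <- (seq_len(geometry$ny) - 0.5) * geometry$dx
  inside <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= 6.25^2
  region <- which(inside)
  p <- new_protocol("decremental",
                    data.frame(onset = onsets, duration = 2, amplitude = -2000),
                    region, geometry)
  p$variant <- params$variant
  p
}

.trajectory_cache <- new.env(parent = emptyenv())

#' One-cycle action potential trajectory of a variant
#'
#' Records the full cell state at 1 ms resolution over one pacing cycle,
#' after conditioning: 40 beats at 1,000 ms, then adaptation beats at the
#' trajectory cycle length. The default trajectory cycle length is 1,000 ms
#' for the normal variant and 400 ms for the remodelled variant (whose APD
#' restitution admits the shorter cycle). Used by [build_spiral_state()].
#'
#' @param variant Cell variant.
#' @param cycle_length Trajectory cycle length, ms (`NULL` for the default).
#' @param n_adapt Adaptation beats at `cycle_length` before recording.
#' @return List with `t` (ms, from the beat onset), `states` (19 x n matrix)
#'   and `cycle_length`.
#' @export
cycle_trajectory <- function(variant, cycle_length = NULL, n_adapt = 5) {
  params <- as_variant_params(variant)
  if (is.null(cycle_length)) {
    cycle_length <- if (params$variant == "normal") 1000 else 400
  }
  key <- sprintf("%s_%g_%d", params$variant, cycle_length, n_adapt)
  if (!is.null(.trajectory_cache[[key]])) return(.trajectory_cache[[key]])
  state <- initialize_variant(params)
  res <- pace_cell(params, cycle_length = cycle_length, n_beats = n_adapt + 1,
                   state = state, record_beats = 1, record_interval = 1)
  out <- list(t = res$t - min(res$t), states = res$states,
              cycle_length = cycle_length)
  .trajectory_cache[[key]] <- out
  out
}

#' Spiral-wave initial condition by the phase-distribution method
#'
#' Builds a full per-node tissue state imposing an Archimedean spiral: each
#' non-fibrotic node is assigned the complete cell state sampled (with
#' linear interpolation) from a one-cycle action potential trajectory at the
#' phase `phi(x, y) = (chirality * theta + 2 * pi * r / pitch) mod 2 * pi`,
#' where `(r, theta)` are polar coordinates about the spiral centre
#' (`theta = 0` at `r = 0` by convention) and phase maps linearly onto
#' trajectory time. Fibrotic nodes are set to the variant's resting state.
#'
#' @param variant Cell variant.
#' @param geometry A [tissue_geometry()].
#' @param field Optional `diffusion_field` supplying the fibrotic mask.
#' @param center Spiral centre in mm, default the domain centre.
#' @param pitch Radial period of the spiral, mm; must be positive.
#' @param chirality `+1` (counter-clockwise) or `-1`.
#' @param cycle_length Trajectory cycle length, ms (`NULL` for the variant
#'   default used by [cycle_trajectory()]).
#' @return A 19 x (nx*ny) state matrix for [run_simulation()]'s `init_state`.
#' @export
build_spiral_state <- function(variant, geometry, field = NULL,
                               center = NULL, pitch = 60, chirality = 1,
                               cycle_length = NULL) {
  if (pitch <= 0) stop("spiral pitch must be positive")
  params <- as_variant_params(variant)
  traj <- cycle_trajectory(params, cycle_length)
  Tcyc <- traj$cycle_length
  if (is.null(center)) {
    center <- c(geometry$nx * geometry$dx / 2, geometry$ny * geometry$dx / 2)
  }
  xs <- (seq_len(geometry$nx) - 0.5) * geometry$dx
  ys <- (seq_len(geometry$ny) - 0.5) * geometry$dx
  X <- matrix(xs, geometry$ny, geometry$nx, byrow = TRUE) - center[1]
  Y <- matrix(ys, geometry$ny, geometry$nx) - center[2]
  r <- sqrt(X^2 + Y^2)
  theta <- atan2(Y, X)
  theta[r == 0] <- 0
  phi <- (chirality * theta + 2 * pi * r / pitch) %% (2 * pi)
  tau <- phi / (2 * pi) * Tcyc

  n <- length(tau)
  init <- matrix(0, nrow(traj$states), n)
  tt <- c(traj$t, Tcyc)
  for (k in seq_len(nrow(traj$states))) {
    vv <- c(traj$states[k, ], traj$states[k, 1]) # periodic closure
    init[k, ] <- stats::approx(tt, vv, xout = as.vector(tau), rule = 2)$y
  }
  if (!is.null(field)) {
    rest <- initialize_variant(params)
    init[, as.vector(field$fibrotic)] <- rest
  }
  rownames(init) <- rownames(traj$states)
  init
}

#' Serialize / restore a pacing protocol
#'
#' Protocols round-trip losslessly through a plain JSON representation.
#'
#' @param protocol A `pacing_protocol`.
#' @return `protocol_to_json()`: a JSON string; `protocol_from_json()`: a
#'   `pacing_protocol`.
#' @export
protocol_to_json <- function(protocol) {
  stopifnot(inherits(protocol, "pacing_protocol"))
  jsonlite::toJSON(list(
    kind = protocol$kind, events = protocol$events, region = protocol$region,
    geometry = unclass(protocol$geometry)[c("nx", "ny", "dx")],
    variant = protocol$variant %||% NULL
  ), auto_unbox = TRUE, digits = NA)
}

#' @rdname protocol_to_json
#' @param json A JSON string produced by `protocol_to_json()`.
#' @export
protocol_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  geom <- tissue_geometry(x$geometry$nx, x$geometry$ny, x$geometry$dx)
  p <- new_protocol(x$kind, as.data.frame(x$events), x$region, geom)
  if (!is.null(x$variant)) p$variant <- x$variant
  p
}
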