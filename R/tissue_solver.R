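#' Tissue geometry
#'
#' The study domain is a 10 x 10 cm sheet discretized as 400 x 400 nodes at
#' 0.25 mm spacing with no-flux boundaries; reduced grids are accepted for
#' tests and smoke runs. Node `(i, j)` (row i = y, column j = x) has its
#' centre at `((j - 1/2) dx, (i - 1/2) dx)` with the origin at the lower-left
#' corner.
#'
#' @param nx,ny Grid points in x and y.
#' @param dx Space step, mm.
#' @return A `tissue_geometry` object.
#' @export
tissue_geometry <- function(nx = 400, ny = 400, dx = 0.25) {
  stopifnot(nx >= 2, ny >= 2, dx > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx,
                 Lx = nx * dx, Ly = ny * dx),
            class = "tissue_geometry")
}

#' @export
print.tissue_geometry <- function(x, ...) {
  cat(sprintf("tissue_geometry: %d x %d nodes, dx = %g mm (%.1f x %.1f mm), no-flux boundaries\n",
              x$nx, x$ny, x$dx, x$Lx, x$Ly))
  invisible(x)
}

# node index (column-major, matching R matrices) for row i, column j
node_index <- function(i, j, ny) (j - 1L) * ny + i

#' Adaptive time step choice
#'
#' Returns the fine step (0.01 ms) whenever a stimulus is active or the
#' maximum |dV/dt| over nodes on the previous step exceeds the trigger
#' (5 mV/ms); otherwise the coarse step, which is the nominal maximum
#' (0.1 ms) clamped to the explicit stability bound `dx^2 / (4 D_max)` of
#' the 2D diffusion stencil.
#'
#' @param D_max Maximum diffusion coefficient in the field, mm^2/ms.
#' @param dx Space step, mm.
#' @param stimulus_active Is any stimulus being delivered?
#' @param max_dvdt Maximum |dV/dt| over nodes on the previous step, mV/ms.
#' @param dt_fine,dt_max Fine step and nominal maximum step, ms.
#' @param dvdt_trigger Threshold on `max_dvdt`, mV/ms.
#' @return Time step in ms.
#' @export
#' @examples
#' choose_dt(D_max = 0.2, dx = 0.25)                         # 0.078125
#' choose_dt(D_max = 0.2, dx = 0.25, stimulus_active = TRUE) # 0.01
choose_dt <- function(D_max, dx, stimulus_active = FALSE, max_dvdt = 0,
                      dt_fine = 0.01, dt_max = 0.1, dvdt_trigger = 5) {
  if (stimulus_active || abs(max_dvdt) > dvdt_trigger) return(dt_fine)
  min(dt_max, dx^2 / (4 * D_max))
}

as_variant_params <- function(variant) {
  if (inherits(variant, "crn_parameters")) variant else cell_parameters(variant)
}

#' Run a monodomain tissue simulation
#'
#' Advances the monodomain reaction-diffusion model
#' `dV/dt = div(D grad V) - (I_ion + I_stim)/Cm` on the 2D sheet defined by
#' `field`, using a flux-conservative 5-point stencil with arithmetic-mean
#' face diffusivities, no-flux boundaries, Rush-Larsen gate integration and
#' the adaptive time step of [choose_dt()]. Fibrotic nodes are coupled but
#' inexcitable: their membrane current term is zero and they evolve by
#' voltage diffusion alone, starting from the variant's resting voltage.
#'
#' All non-fibrotic nodes start from the variant's steady paced state
#' ([initialize_variant()]) unless `init_state` supplies a full per-node
#' state (as built by [build_spiral_state()]).
#'
#' Threshold crossings of every node's voltage (default -73.0 mV) are
#' detected during the run with linear interpolation in time and returned
#' for map construction, together with probe voltage traces sampled at
#' `probe_interval`.
#'
#' @param field A `diffusion_field`.
#' @param variant `"normal"`, `"remodelled"` or a [cell_parameters()] object.
#' @param protocol A `pacing_protocol`, or `NULL` for stimulus-free runs
#'   (e.g. evolving a spiral initial condition).
#' @param duration Simulated time, ms.
#' @param probes Integer node indices (column-major) of voltage probes,
#'   `"default"` for the standard 3 x 3 lattice of [default_probes()], or
#'   `NULL` for none.
#' @param init_state Optional 19 x (nx*ny) matrix of per-node initial states.
#' @param record_frames Record voltage frames every `frame_interval` ms
#'   (memory-heavy on large grids; intended for plots and small runs).
#' @param frame_interval Frame sampling interval, ms.
#' @param probe_interval Probe sampling interval, ms.
#' @param threshold Crossing-detection threshold, mV.
#' @param max_crossings Crossing records kept per node.
#' @param dt_fine,dt_max,dvdt_trigger Adaptive time-step policy (see
#'   [choose_dt()]).
#' @return A `voltage_recording` object.
#' @export
run_simulation <- function(field, variant, protocol = NULL, duration,
                           probes = NULL, init_state = NULL,
                           record_frames = FALSE, frame_interval = 1,
                           probe_interval = 0.5, threshold = -73,
                           max_crossings = 40, dt_fine = 0.01, dt_max = 0.1,
                           dvdt_trigger = 5) {
  stopifnot(inherits(field, "diffusion_field"), duration > 0)
  params <- as_variant_params(variant)
  if (!is.null(protocol)) {
    stopifnot(inherits(protocol, "pacing_protocol"))
    if (nrow(protocol$events) > 0) {
      tmax <- max(protocol$events$onset + protocol$events$duration)
      if (tmax > duration) {
        stop("protocol extends to ", tmax, " ms, beyond duration ", duration, " ms")
      }
    }
    events <- protocol$events
    region <- protocol$region
  } else {
    events <- data.frame(onset = numeric(0), duration = numeric(0),
                         amplitude = numeric(0))
    region <- integer(0)
  }
  if (is.null(init_state)) {
    init_state <- matrix(initialize_variant(params), ncol = 1)
  }
  if (identical(probes, "default")) {
    probes <- default_probes(tissue_geometry(field$nx, field$ny, field$dx), field)
  }
  probes <- as.integer(probes %||% integer(0))

  res <- cpp_tissue_run(field$D, field$fibrotic, field$dx, init_state,
                        param_scales(params),
                        events$onset, events$duration, events$amplitude,
                        region - 1L, duration, frame_interval,
                        probes - 1L, threshold, as.integer(max_crossings),
                        dt_fine, dt_max, dvdt_trigger, record_frames,
                        probe_interval)
  structure(list(
    t_up = res$t_up, t_down = res$t_down,
    n_up = res$n_up, n_down = res$n_down,
    probe_t = res$probe_t, probe_V = res$probe_V, probes = probes,
    frames = if (record_frames) res$frames else NULL,
    n_frames = res$n_frames, frame_interval = frame_interval,
    final_state = res$final_state,
    geometry = tissue_geometry(field$nx, field$ny, field$dx),
    fibrotic = field$fibrotic, field_dialect = field$dialect,
    field_spec = field$spec, variant = params$variant,
    protocol = protocol, threshold = threshold, duration = duration,
    n_steps = res$n_steps, dt_coarse = res$dt_coarse),
    class = "voltage_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.voltage_recording <- function(x, ...) {
  cat(sprintf("voltage_recording: %d x %d nodes, %g ms, variant %s, %s\n",
              x$geometry$nx, x$geometry$ny, x$duration, x$variant,
              if (is.null(x$protocol)) "no stimuli" else
                sprintf("protocol '%s' (%d stimuli)", x$protocol$kind,
                        nrow(x$protocol$events))))
  cat(sprintf("  %d solver steps; %d probes; activated nodes: %d/%d\n",
              x$n_steps, length(x$probes), sum(x$n_up > 0),
              x$geometry$nx * x$geometry$ny))
  invisible(x)
}

#' Plane-wave conduction velocity
#'
#' Measures conduction velocity in a thin strip of uniform tissue paced along
#' its full left edge, as the distance between two measurement columns
#' divided by the difference of their activation times (first upward
#' crossings of -73.0 mV). The columns must be at least 25 mm apart and
#' 25 mm from either end so that the front is planar and boundary effects
#' are excluded.
#'
#' @param variant Cell variant (name or [cell_parameters()]).
#' @param D_uniform Uniform diffusion coefficient, mm^2/ms.
#' @param nx,ny,dx Strip geometry (defaults: 400 x 20 nodes at 0.25 mm).
#' @param x1,x2 Measurement column positions, mm.
#' @param stim_amplitude,stim_duration Edge stimulus (pA, ms).
#' @param dt_fine,dt_max Adaptive time-step bounds passed to
#'   [run_simulation()] (for convergence checks).
#' @return Conduction velocity in mm/ms.
#' @export
plane_wave_cv <- function(variant, D_uniform = 0.2, nx = 400, ny = 20,
                          dx = 0.25, x1 = 30, x2 = 70,
                          stim_amplitude = -2000, stim_duration = 2,
                          dt_fine = 0.01, dt_max = 0.1) {
  stopifnot(x2 > x1)
  L <- nx * dx
  if (x2 - x1 < 25 || x1 < 25 || L - x2 < 25) {
    stop("measurement columns must be >= 25 mm apart and >= 25 mm from the edges")
  }
  field <- uniform_diffusion_field(nx, ny, dx, D_uniform)
  geom <- tissue_geometry(nx, ny, dx)
  # stimulate a 2.5 mm deep band along the full left edge (a thinner band
  # loses its injected charge diffusively and fails to capture)
  nb <- max(1L, round(2.5 / dx))
  region <- as.integer(outer(seq_len(ny), (seq_len(nb) - 1L) * ny, `+`))
  proto <- new_protocol("s1", data.frame(onset = 0, duration = stim_duration,
                                         amplitude = stim_amplitude),
                        region, geom)
  j1 <- max(1L, round(x1 / dx))
  j2 <- max(1L, round(x2 / dx))
  if (j1 == j2) stop("measurement columns are identical")
  mid <- as.integer(ceiling(ny / 2))
  # generous travel-time allowance (CV scales roughly with sqrt(D))
  duration <- 20 + L / (0.4 * sqrt(D_uniform / 0.2))
  rec <- run_simulation(field, variant, proto, duration = duration,
                        dt_fine = dt_fine, dt_max = dt_max)
  t1 <- rec$t_up[1, node_index(mid, j1, ny)]
  t2 <- rec$t_up[1, node_index(mid, j2, ny)]
  if (is.na(t1) || is.na(t2)) stop("measurement column not activated")
  (j2 - j1) * dx / (t2 - t1)
}

#' Corner-paced conduction velocity in a square sheet
#'
#' Measures the effective conduction velocity of the convex wave elicited by
#' a corner stimulus in a uniform square sheet (the S1 configuration of the
#' full-field maps): activation times are read at two points on the main
#' diagonal, at fractions `f1` and `f2` of the diagonal length, and CV is the
#' distance between them divided by the activation-time difference. The
#' wavefront propagates diagonally to the grid there, so this measurement
#' includes wavefront-curvature and grid-orientation effects absent from
#' [plane_wave_cv()].
#'
#' @param variant Cell variant.
#' @param D_uniform Uniform diffusion coefficient, mm^2/ms.
#' @param nx,ny,dx Sheet geometry.
#' @param f1,f2 Measurement points as fractions of the diagonal.
#' @return Conduction velocity in mm/ms.
#' @export
corner_paced_cv <- function(variant, D_uniform = 0.2, nx = 400, ny = 400,
                            dx = 0.25, f1 = 0.35, f2 = 0.65) {
  stopifnot(f2 > f1, f1 > 0, f2 < 1)
  field <- uniform_diffusion_field(nx, ny, dx, D_uniform)
  geom <- tissue_geometry(nx, ny, dx)
  proto <- corner_stimulus_protocol(geom, onsets = 0)
  i1 <- max(1L, round(f1 * ny)); j1 <- max(1L, round(f1 * nx))
  i2 <- max(1L, round(f2 * ny)); j2 <- max(1L, round(f2 * nx))
  L <- sqrt((nx * dx)^2 + (ny * dx)^2)
  duration <- 20 + f2 * L / (0.35 * sqrt(D_uniform / 0.2))
  rec <- run_simulation(field, variant, proto, duration = duration)
  t1 <- rec$t_up[1, node_index(i1, j1, ny)]
  t2 <- rec$t_up[1, node_index(i2, j2, ny)]
  if (is.na(t1) || is.na(t2)) stop("measurement point not activated")
  sqrt((i2 - i1)^2 + (j2 - j1)^2) * dx / (t2 - t1)
}
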