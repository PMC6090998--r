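# shared test fixtures, all built in code

# rectangular voltage pulse trace: -80 mV baseline, 0 mV during [on, off)
rect_trace <- function(on, off, t_end = 400, dt = 1, v_hi = 0, v_lo = -80) {
  t <- seq(0, t_end, by = dt)
  V <- ifelse(t >= on & t < off, v_hi, v_lo)
  list(t = t, V = V)
}

# minimal synthetic voltage_recording carrying per-node crossing times
# (K x N matrices) and optional probe traces, for analysis-layer tests
fake_recording <- function(t_up, t_down, ny, nx, fibrotic = NULL,
                           probe_t = numeric(0), probe_V = NULL,
                           probes = integer(0), threshold = -73) {
  K <- nrow(t_up)
  structure(list(
    t_up = t_up, t_down = t_down,
    n_up = colSums(!is.na(t_up)), n_down = colSums(!is.na(t_down)),
    probe_t = probe_t,
    probe_V = if (is.null(probe_V)) matrix(0, 0, 0) else probe_V,
    probes = probes, frames = NULL, n_frames = 0L, frame_interval = 1,
    final_state = NULL,
    geometry = tissue_geometry(nx, ny, 0.25),
    fibrotic = if (is.null(fibrotic)) matrix(FALSE, ny, nx) else fibrotic,
    field_dialect = "uniform", field_spec = NULL, variant = "normal",
    protocol = NULL, threshold = threshold, duration = Inf,
    n_steps = 0L, dt_coarse = 0.1), class = "voltage_recording")
}

# single-beat activation map built directly from matrices
fake_map <- function(t_act, t_rec, valid = NULL) {
  ny <- nrow(t_act); nx <- ncol(t_act)
  if (is.null(valid)) valid <- !is.na(t_act) & !is.na(t_rec)
  t_act[!valid] <- NA; t_rec[!valid] <- NA
  structure(list(beats = list(list(t_act = t_act, t_rec = t_rec,
                                   apd = t_rec - t_act, valid = valid,
                                   window = c(0, Inf))),
                 geometry = tissue_geometry(nx, ny, 0.25), threshold = -73),
            class = "activation_map")
}
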