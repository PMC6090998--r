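#' Detect threshold excursions in a voltage trace
#'
#' Finds the ordered, non-overlapping intervals during which a uniformly
#' sampled voltage trace sits above a threshold (default -73.0 mV). Crossing
#' times are linearly interpolated between samples. Excursions shorter than
#' `min_width` ms are discarded as numerical glitches. An excursion still
#' open at the end of the trace has `t_down = NA`; a trace that starts above
#' threshold contributes no leading excursion (its onset is unobserved).
#'
#' @param t Sample times, ms (uniform spacing).
#' @param V Voltages, mV.
#' @param threshold Threshold, mV.
#' @param min_width Minimum excursion width, ms.
#' @return A data frame with columns `t_up` and `t_down` (ms).
#' @export
#' @examples
#' t <- 0:300
#' V <- ifelse(t >= 10 & t < 110, 0, -80)
#' detect_crossings(t, V)
detect_crossings <- function(t, V, threshold = -73, min_width = 5) {
  stopifnot(length(t) == length(V), length(t) >= 2)
  n <- length(V)
  below <- V < threshold
  up_i <- which(below[-n] & !below[-1])
  down_i <- which(!below[-n] & below[-1])
  frac <- function(i) (threshold - V[i]) / (V[i + 1] - V[i])
  t_up <- t[up_i] + frac(up_i) * (t[up_i + 1] - t[up_i])
  t_down <- t[down_i] + frac(down_i) * (t[down_i + 1] - t[down_i])
  # drop a leading down-crossing (trace started above threshold)
  if (length(t_down) > 0 && (length(t_up) == 0 || t_down[1] < t_up[1])) {
    t_down <- t_down[-1]
  }
  if (length(t_up) == 0) {
    return(data.frame(t_up = numeric(0), t_down = numeric(0)))
  }
  length(t_down) <- length(t_up) # pad an open excursion with NA
  keep <- is.na(t_down) | (t_down - t_up >= min_width)
  data.frame(t_up = t_up[keep], t_down = t_down[keep])
}

# pair per-node up/down crossing matrices (max_crossings x N) into excursion
# matrices, dropping excursions shorter than min_width
pair_crossings <- function(t_up, t_down, min_width = 5) {
  K <- nrow(t_up)
  N <- ncol(t_up)
  # if the first recorded crossing is a down-crossing, the node started above
  # threshold: discard that down-crossing
  shift <- !is.na(t_down[1, ]) &
    (is.na(t_up[1, ]) | t_down[1, ] < t_up[1, ])
  if (any(shift)) {
    idx <- which(shift)
    t_down[, idx] <- rbind(t_down[-1, idx, drop = FALSE],
                           rep(NA_real_, length(idx)))
  }
  width <- t_down - t_up
  short <- !is.na(width) & width < min_width
  t_up[short] <- NA_real_
  t_down[short] <- NA_real_
  list(t_up = t_up, t_down = t_down)
}

#' Build per-beat activation/recovery/APD maps from a recording
#'
#' For each beat window, the activation time of a node is its first upward
#' threshold crossing inside the window and the recovery time is the
#' matching downward crossing (which may fall beyond the window). APD is
#' their difference. Fibrotic nodes and nodes without a complete excursion
#' in the window are invalid; activation, recovery and APD are not reported
#' for them even when passive voltage excursions cross the threshold.
#'
#' @param recording A `voltage_recording`.
#' @param field The `diffusion_field` the recording was made on (supplies
#'   the fibrotic mask); `NULL` uses the mask stored in the recording.
#' @param beat_windows List of `c(start, end)` intervals (ms), typically
#'   from [beat_windows_from_protocol()]. Must not overlap.
#' @param min_width Excursion debounce width, ms.
#' @return An `activation_map` object: per beat, `ny` x `nx` matrices
#'   `t_act`, `t_rec`, `apd` and logical `valid`.
#' @export
build_maps <- function(recording, field = NULL, beat_windows, min_width = 5) {
  stopifnot(inherits(recording, "voltage_recording"))
  fib <- if (is.null(field)) recording$fibrotic else field$fibrotic
  ny <- recording$geometry$ny
  nx <- recording$geometry$nx
  w <- do.call(rbind, beat_windows)
  if (nrow(w) > 1) {
    o <- order(w[, 1])
    if (any(w[o, 1][-1] < w[o, 2][-nrow(w)])) stop("beat windows overlap")
  }
  pr <- pair_crossings(recording$t_up, recording$t_down, min_width)
  beats <- vector("list", length(beat_windows))
  for (b in seq_along(beat_windows)) {
    win <- beat_windows[[b]]
    t_act <- rep(NA_real_, nx * ny)
    t_rec <- rep(NA_real_, nx * ny)
    for (k in seq_len(nrow(pr$t_up))) {
      up <- pr$t_up[k, ]
      sel <- !is.na(up) & up >= win[1] & up < win[2] & is.na(t_act)
      t_act[sel] <- up[sel]
      t_rec[sel] <- pr$t_down[k, sel]
    }
    valid <- !is.na(t_act) & !is.na(t_rec) & !as.vector(fib)
    t_act[!valid] <- NA_real_
    t_rec[!valid] <- NA_real_
    beats[[b]] <- list(
      t_act = matrix(t_act, ny, nx), t_rec = matrix(t_rec, ny, nx),
      apd = matrix(t_rec - t_act, ny, nx), valid = matrix(valid, ny, nx),
      window = win)
  }
  structure(list(beats = beats, geometry = recording$geometry,
                 threshold = recording$threshold),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("activation_map: %d beat(s), %d x %d nodes\n", length(x$beats),
              x$geometry$nx, x$geometry$ny))
  for (b in seq_along(x$beats)) {
    bt <- x$beats[[b]]
    cat(sprintf("  beat %d [%g, %g) ms: %d valid nodes, median APD %.1f ms\n",
                b, bt$window[1], bt$window[2], sum(bt$valid),
                stats::median(bt$apd[bt$valid])))
  }
  invisible(x)
}

#' Beat windows from a protocol
#'
#' Window `i` spans from stimulus onset `i` to onset `i+1`; the final window
#' is extended by `tail` ms so the last beat's activation is captured
#' (recovery may complete beyond the window).
#'
#' @param protocol A `pacing_protocol`.
#' @param tail Extension of the final window, ms.
#' @return List of `c(start, end)` windows.
#' @export
beat_windows_from_protocol <- function(protocol, tail = 500) {
  on <- protocol$events$onset
  stopifnot(length(on) >= 1)
  ends <- c(on[-1], on[length(on)] + tail)
  Map(c, on, ends)
}

#' Delay statistics between a heterogeneous map and a uniform baseline
#'
#' Node-wise activation and recovery delays (heterogeneous minus uniform)
#' over the nodes valid in both maps, summarized by median and interquartile
#' range, plus the APD summary of the heterogeneous map. If fewer than half
#' the nodes valid in the baseline are comparable the summary is flagged
#' `low_overlap`.
#'
#' @param map_het,map_uniform `activation_map`s on the same geometry.
#' @param beat Beat index to compare.
#' @return A list of summary statistics (ms).
#' @export
delay_stats <- function(map_het, map_uniform, beat = 1) {
  bh <- map_het$beats[[beat]]
  bu <- map_uniform$beats[[beat]]
  stopifnot(identical(dim(bh$t_act), dim(bu$t_act)))
  common <- bh$valid & bu$valid
  act <- bh$t_act[common] - bu$t_act[common]
  rec <- bh$t_rec[common] - bu$t_rec[common]
  apd <- bh$apd[bh$valid]
  iqr <- function(x) unname(diff(stats::quantile(x, c(0.25, 0.75))))
  list(
    median_act_delay = stats::median(act), iqr_act_delay = iqr(act),
    median_rec_delay = stats::median(rec), iqr_rec_delay = iqr(rec),
    median_apd = stats::median(apd), iqr_apd = iqr(apd),
    apd_skewness = skewness_fp(apd),
    n_common = sum(common),
    low_overlap = sum(common) < 0.5 * sum(bu$valid)
  )
}

#' Adjusted Fisher-Pearson skewness coefficient
#'
#' `n / ((n-1)(n-2)) * sum(((x - mean) / s)^3)` with `s` the sample standard
#' deviation.
#'
#' @param x Numeric vector (NAs removed).
#' @return Skewness (dimensionless).
#' @export
skewness_fp <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(0)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}

#' Pooled APD distribution across maps
#'
#' Pools valid-node APD values from one beat of each map and returns a
#' histogram, quartiles and the moment skewness coefficient.
#'
#' @param maps A single `activation_map` or a list of them.
#' @param beat Beat index to pool.
#' @param breaks Passed to [graphics::hist()].
#' @return A list with `apd` (pooled values), `quartiles`, `skewness` and
#'   `histogram`.
#' @export
apd_distribution <- function(maps, beat = 1, breaks = "Sturges") {
  if (inherits(maps, "activation_map")) maps <- list(maps)
  apd <- unlist(lapply(maps, function(m) {
    bt <- m$beats[[beat]]
    bt$apd[bt$valid]
  }))
  if (length(apd) == 0) stop("no valid nodes in the supplied maps")
  list(apd = apd,
       quartiles = stats::quantile(apd, c(0.25, 0.5, 0.75)),
       skewness = skewness_fp(apd),
       histogram = graphics::hist(apd, breaks = breaks, plot = FALSE))
}

#' Count beats, blocked stimuli and sustained re-entry at probes
#'
#' A beat is an upward threshold excursion at a probe; the beat count is the
#' maximum over probes. Stimulus `i` is blocked when no probe activates
#' within `block_window` ms of its onset. Re-entry is sustained when more
#' than 15 activations occur after the final stimulus (plus the block
#' window).
#'
#' @param recording A `voltage_recording` with probe traces.
#' @param protocol The `pacing_protocol` that drove the recording.
#' @param probes Optional subset of the recording's probes (node indices).
#' @param block_window Time allowed for a stimulus to produce an activation, ms.
#' @param min_width Excursion debounce width, ms.
#' @return A list with `n_beats`, `blocked_stimuli` (stimulus indices) and
#'   `sustained` (logical).
#' @export
count_beats <- function(recording, protocol, probes = NULL,
                        block_window = 200, min_width = 5) {
  stopifnot(inherits(recording, "voltage_recording"),
            length(recording$probes) >= 1)
  sel <- if (is.null(probes)) seq_along(recording$probes) else {
    m <- match(probes, recording$probes)
    if (anyNA(m)) stop("requested probes not present in the recording")
    m
  }
  if (any(recording$probes[sel] %in% protocol$region)) {
    stop("probes must lie outside the stimulus region")
  }
  ups <- lapply(sel, function(p) {
    detect_crossings(recording$probe_t, recording$probe_V[, p],
                     threshold = recording$threshold,
                     min_width = min_width)$t_up
  })
  n_beats <- max(vapply(ups, length, integer(1)))
  onsets <- protocol$events$onset
  blocked <- which(vapply(onsets, function(on) {
    !any(vapply(ups, function(u) any(u >= on & u <= on + block_window),
                logical(1)))
  }, logical(1)))
  t_end <- max(onsets) + block_window
  post <- max(vapply(ups, function(u) sum(u > t_end), integer(1)))
  list(n_beats = n_beats, blocked_stimuli = blocked, sustained = post > 15,
       post_protocol_beats = post)
}

#' Default probe lattice
#'
#' A 3 x 3 lattice of probes at 25%, 50% and 75% of each dimension, each
#' shifted to the nearest non-fibrotic node.
#'
#' @param geometry A [tissue_geometry()].
#' @param field Optional `diffusion_field` whose fibrotic mask probes must
#'   avoid.
#' @return Integer node indices (column-major).
#' @export
default_probes <- function(geometry, field = NULL) {
  fr <- c(0.25, 0.5, 0.75)
  ii <- pmax(1L, round(fr * geometry$ny))
  jj <- pmax(1L, round(fr * geometry$nx))
  probes <- as.integer(outer(ii, (jj - 1L) * geometry$ny, `+`))
  if (!is.null(field) && any(field$fibrotic[probes])) {
    ok <- which(!field$fibrotic)
    if (length(ok) == 0) stop("field is entirely fibrotic")
    iy_ok <- (ok - 1L) %% geometry$ny + 1L
    jx_ok <- (ok - 1L) %/% geometry$ny + 1L
    probes <- vapply(probes, function(p) {
      if (!field$fibrotic[p]) return(p)
      iy <- (p - 1L) %% geometry$ny + 1L
      jx <- (p - 1L) %/% geometry$ny + 1L
      ok[which.min((iy_ok - iy)^2 + (jx_ok - jx)^2)]
    }, integer(1))
  }
  unique(probes)
}

#' Re-entry wavelength
#'
#' The wavelength, minimum APD times conduction velocity, is the tissue
#' length a circulating wave occupies; excitable tissue must accommodate it
#' for re-entry to persist.
#'
#' @param apd Action potential duration, ms (positive).
#' @param cv Conduction velocity, mm/ms (positive).
#' @return Wavelength in mm.
#' @export
#' @examples
#' wavelength(300, 0.5)
wavelength <- function(apd, cv) {
  if (any(apd <= 0) || any(cv <= 0)) stop("apd and cv must be positive")
  apd * cv
}

#' Export activation isochrones
#'
#' Level sets of the activation-time map at a fixed interval, as plain
#' polylines suitable for plotting or text export.
#'
#' @param map An `activation_map`.
#' @param interval Isochrone spacing, ms.
#' @param beat Beat index.
#' @return A list of contours, each with `level` (ms) and `x`, `y`
#'   coordinates in mm; empty when the map has no valid nodes.
#' @export
isochrone_export <- function(map, interval = 25, beat = 1) {
  bt <- map$beats[[beat]]
  if (!any(bt$valid)) return(list())
  rng <- range(bt$t_act, na.rm = TRUE)
  # interior levels only: a level at the exact map minimum or maximum is a
  # degenerate (empty) contour
  lev0 <- interval * floor(rng[1] / interval + 1)
  if (lev0 > rng[2]) return(list())
  levels <- seq(lev0, rng[2], by = interval)
  levels <- levels[levels < rng[2]]
  if (length(levels) == 0) return(list())
  xs <- (seq_len(map$geometry$nx) - 0.5) * map$geometry$dx
  ys <- (seq_len(map$geometry$ny) - 0.5) * map$geometry$dx
  z <- bt$t_act
  z[!bt$valid] <- NA
  grDevices::contourLines(xs, ys, t(z), levels = levels)
}

#' @export
plot.activation_map <- function(x, beat = 1, what = c("t_act", "t_rec", "apd"),
                                ...) {
  what <- match.arg(what)
  bt <- x$beats[[beat]]
  z <- bt[[what]]
  z[!bt$valid] <- NA
  xs <- (seq_len(x$geometry$nx) - 0.5) * x$geometry$dx
  ys <- (seq_len(x$geometry$ny) - 0.5) * x$geometry$dx
  graphics::image(xs, ys, t(z), xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("%s (ms), beat %d", what, beat),
                  useRaster = TRUE, ...)
  invisible(x)
}
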