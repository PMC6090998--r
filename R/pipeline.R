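#' Study configuration
#'
#' Describes a simulation grid: correlation lengths x samples x cell
#' variants x protocols x field dialects. The `"study"` preset is the full
#' grid (four length scales, 20 samples, both variants, smooth and binary
#' fields on the 400 x 400 sheet: hours of compute). The `"smoke"` preset is
#' a desk-scale version on a reduced grid for testing the pipeline.
#'
#' @param preset `"smoke"` or `"study"`.
#' @param ... Overrides for any configuration field (`deltas`, `n_samples`,
#'   `variants`, `protocols`, `dialects`, `base_seed`, `nx`, `ny`, `dx`,
#'   `output_root`).
#' @return A `study_config` object.
#' @export
#' @examples
#' study_config("smoke", n_samples = 1)
study_config <- function(preset = c("smoke", "study"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "study") {
    list(deltas = c(1.25, 2.5, 5, 10), n_samples = 20,
         variants = c("normal", "remodelled"),
         protocols = c("s1s2", "decremental"),
         dialects = c("smooth", "binary"),
         base_seed = 1, nx = 400, ny = 400, dx = 0.25,
         output_root = NULL)
  } else {
    list(deltas = c(1.25, 2.5), n_samples = 2,
         variants = c("normal", "remodelled"),
         protocols = "s1s2", dialects = "smooth",
         base_seed = 1, nx = 100, ny = 100, dx = 0.25,
         output_root = NULL)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg$preset <- preset
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("study_config ('%s'): %d x %d nodes at dx = %g mm\n", x$preset,
              x$nx, x$ny, x$dx))
  cat(sprintf("  deltas: %s mm; %d sample(s); variants: %s\n",
              paste(x$deltas, collapse = ", "), x$n_samples,
              paste(x$variants, collapse = ", ")))
  cat(sprintf("  protocols: %s; dialects: %s; base seed %d\n",
              paste(x$protocols, collapse = ", "),
              paste(x$dialects, collapse = ", "), x$base_seed))
  invisible(x)
}

config_key <- function(...) {
  paste(vapply(list(...), function(x) paste(format(x), collapse = "_"),
               character(1)), collapse = "__")
}

run_duration <- function(protocol, tail = 800) {
  max(protocol$events$onset + protocol$events$duration) + tail
}

# run one (field, variant, protocol) cell of the grid and summarize it
summarize_run <- function(field, variant, protocol_kind, geometry,
                          baseline_maps, tail = 800) {
  proto <- switch(protocol_kind,
                  s1s2 = build_s1s2(geometry),
                  decremental = build_decremental(variant, geometry),
                  stop("unknown protocol: ", protocol_kind))
  probes <- default_probes(geometry, field)
  probes <- setdiff(probes, proto$region)
  rec <- run_simulation(field, variant, proto, duration = run_duration(proto, tail),
                        probes = probes)
  wins <- beat_windows_from_protocol(proto, tail = tail)
  maps <- build_maps(rec, field, wins)
  beats <- count_beats(rec, proto)
  # summary beat: last S1 for s1s2 (beat 3); S2 is beat 4
  main_beat <- if (protocol_kind == "s1s2") 3L else 1L
  ds <- if (!is.null(baseline_maps)) {
    delay_stats(maps, baseline_maps, beat = main_beat)
  } else {
    bt <- maps$beats[[main_beat]]
    apd <- bt$apd[bt$valid]
    list(median_act_delay = NA_real_, iqr_act_delay = NA_real_,
         median_rec_delay = NA_real_, iqr_rec_delay = NA_real_,
         median_apd = if (length(apd)) stats::median(apd) else NA_real_,
         iqr_apd = if (length(apd)) unname(diff(stats::quantile(apd, c(0.25, 0.75)))) else NA_real_,
         apd_skewness = skewness_fp(apd), n_common = NA_integer_,
         low_overlap = FALSE)
  }
  s2 <- if (protocol_kind == "s1s2" && length(maps$beats) >= 4) {
    bt <- maps$beats[[4]]
    apd <- bt$apd[bt$valid]
    if (length(apd)) stats::median(apd) else NA_real_
  } else NA_real_
  c(ds[c("median_act_delay", "iqr_act_delay", "median_rec_delay",
         "iqr_rec_delay", "median_apd", "iqr_apd", "apd_skewness")],
    list(median_apd_s2 = s2, n_beats = beats$n_beats,
         n_blocked = length(beats$blocked_stimuli),
         blocked = paste(beats$blocked_stimuli, collapse = ";"),
         sustained = beats$sustained, low_overlap = isTRUE(ds$low_overlap)))
}

#' Run a study grid
#'
#' Runs every (length scale, sample, variant, protocol, dialect) cell of the
#' configured grid and returns one summary row per run: median and IQR of
#' activation and recovery delay relative to the uniform-diffusion baseline
#' (D = 0.2 mm^2/ms, same variant and protocol), APD summary and skewness,
#' beat counts, blocked stimuli and the sustained re-entry flag. Completed
#' runs are cached as RDS files under `output_root` keyed by their
#' configuration, so an interrupted grid resumes without recomputation;
#' failures are isolated to their run and flagged in the manifest.
#'
#' @param config A [study_config()].
#' @param output_root Cache/output directory (default
#'   `file.path(tempdir(), "fibroscape-study")`).
#' @param verbose Report per-run progress.
#' @return A data frame manifest, one row per run, with the summary columns
#'   above plus provenance (delta, sample, seed, variant, protocol, dialect);
#'   also written to `manifest.csv` under `output_root`.
#' @export
run_study <- function(config, output_root = NULL, verbose = interactive()) {
  stopifnot(inherits(config, "study_config"))
  output_root <- output_root %||% config$output_root %||%
    file.path(tempdir(), "fibroscape-study")
  dir.create(output_root, showWarnings = FALSE, recursive = TRUE)
  geometry <- tissue_geometry(config$nx, config$ny, config$dx)
  ens <- generate_study_ensemble(config$deltas, config$n_samples,
                                 config$base_seed, config$nx, config$ny,
                                 config$dx)
  # uniform baselines per (variant, protocol)
  baselines <- list()
  for (variant in config$variants) {
    for (pk in config$protocols) {
      key <- config_key("baseline", variant, pk, config$nx, config$ny, config$dx)
      f <- file.path(output_root, paste0(key, ".rds"))
      if (file.exists(f)) {
        baselines[[paste(variant, pk)]] <- readRDS(f)
        next
      }
      ufield <- uniform_diffusion_field(config$nx, config$ny, config$dx, 0.2)
      proto <- switch(pk, s1s2 = build_s1s2(geometry),
                      decremental = build_decremental(variant, geometry))
      rec <- run_simulation(ufield, variant, proto,
                            duration = run_duration(proto),
                            probes = default_probes(geometry))
      maps <- build_maps(rec, ufield, beat_windows_from_protocol(proto, tail = 800))
      saveRDS(maps, f)
      baselines[[paste(variant, pk)]] <- maps
      if (verbose) message("baseline: ", variant, " / ", pk)
    }
  }
  rows <- list()
  for (di in seq_along(config$deltas)) {
    for (si in seq_len(config$n_samples)) {
      pair <- ens$fields[[di]][[si]]
      seed <- ens$manifest$seed[ens$manifest$delta == config$deltas[di] &
                                  ens$manifest$sample == si]
      for (dialect in config$dialects) {
        field <- pair[[dialect]]
        for (variant in config$variants) {
          for (pk in config$protocols) {
            key <- config_key("run", config$deltas[di], si, dialect, variant,
                              pk, config$nx, config$ny, config$dx, seed)
            f <- file.path(output_root, paste0(key, ".rds"))
            prov <- data.frame(delta = config$deltas[di], sample = si,
                               seed = seed, dialect = dialect,
                               variant = variant, protocol = pk,
                               stringsAsFactors = FALSE)
            if (file.exists(f)) {
              rows[[key]] <- readRDS(f)
              next
            }
            row <- tryCatch({
              s <- summarize_run(field, variant, pk, geometry,
                                 baselines[[paste(variant, pk)]])
              cbind(prov, as.data.frame(s), failed = FALSE)
            }, error = function(e) {
              cbind(prov, data.frame(
                median_act_delay = NA_real_, iqr_act_delay = NA_real_,
                median_rec_delay = NA_real_, iqr_rec_delay = NA_real_,
                median_apd = NA_real_, iqr_apd = NA_real_,
                apd_skewness = NA_real_, median_apd_s2 = NA_real_,
                n_beats = NA_integer_, n_blocked = NA_integer_,
                blocked = conditionMessage(e), sustained = NA,
                low_overlap = NA), failed = TRUE)
            })
            saveRDS(row, f)
            rows[[key]] <- row
            if (verbose) {
              message(sprintf("run: delta %g sample %d %s %s %s",
                              config$deltas[di], si, dialect, variant, pk))
            }
          }
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(output_root, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

acceptance_targets <- function() {
  list(
    t1 = list(
      description = "diffusion coefficient mapped from a raw field value of +1",
      units = "mm^2/ms", reference = 0.15,
      compute = function() {
        f <- grf_to_diffusion(matrix(1, 2, 2))
        list(value = f$D[1, 1], n = 1)
      }),
    t3 = list(
      description = "single-cell APD, normal variant, cycle length 1,000 ms",
      units = "ms", reference = 300,
      compute = function() {
        list(value = single_cell_apd(cell_parameters("normal"),
                                     cycle_length = 1000),
             n = 40)
      })
  )
}

#' Recompute headline quantities from scratch
#'
#' Computes each named target quantity by running the relevant part of the
#' pipeline and tabulates it next to its reference value.
#'
#' @param targets Character vector of target ids (see
#'   `names(fibroscape:::acceptance_targets())`); an empty vector returns an
#'   empty table.
#' @return A data frame with columns `target`, `description`, `value`,
#'   `units` and `reference`.
#' @export
#' @examples
#' reproduce_report("t1")
reproduce_report <- function(targets = c("t1", "t3")) {
  known <- acceptance_targets()
  bad <- setdiff(targets, names(known))
  if (length(bad) > 0) {
    stop("unknown target id(s): ", paste(bad, collapse = ", "),
         "; known ids: ", paste(names(known), collapse = ", "))
  }
  rows <- lapply(targets, function(id) {
    tg <- known[[id]]
    res <- tg$compute()
    data.frame(target = id, description = tg$description, value = res$value,
               units = tg$units, reference = tg$reference,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(target = character(0), description = character(0),
                      value = numeric(0), units = character(0),
                      reference = numeric(0)))
  }
  do.call(rbind, rows)
}
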