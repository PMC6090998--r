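#' Specification of a stationary Gaussian random field
#'
#' Describes a zero-mean, unit-variance stationary Gaussian random field
#' (GRF) on a regular 2D lattice with squared-exponential covariance
#' `Cov(r) = exp(-r^2 / delta^2)`, where `delta` is the correlation length.
#' The field is sampled at node centres on the same lattice as the tissue
#' solver, so no interpolation is needed.
#'
#' @param nx,ny Grid points in x and y.
#' @param dx Lattice spacing, mm.
#' @param delta Correlation length, mm. The study uses 1.25, 2.5, 5.0 and
#'   10.0 mm; any positive value is accepted provided the domain holds at
#'   least four correlation lengths in each direction.
#' @param seed Integer seed making the sample reproducible.
#' @return An object of class `grf_spec`.
#' @export
grf_spec <- function(nx, ny, dx = 0.25, delta, seed) {
  stopifnot(nx >= 2, ny >= 2, dx > 0, delta > 0)
  if (nx * dx < 4 * delta || ny * dx < 4 * delta) {
    stop("domain (", nx * dx, " x ", ny * dx,
         " mm) must hold at least 4 correlation lengths (delta = ", delta, " mm)")
  }
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx,
                 delta = delta, seed = as.integer(seed), mean = 0, variance = 1),
            class = "grf_spec")
}

# run code with a private RNG stream, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Sample a Gaussian random field by circulant embedding
#'
#' Draws one sample of the stationary GRF described by `spec` using circulant
#' embedding: the squared-exponential covariance is wrapped onto a 2x-padded
#' periodic grid, diagonalized exactly by the 2D FFT, and the sample is the
#' real part of the inverse transform of the spectrally coloured complex
#' white noise. Any negative embedding eigenvalues (the embedding is only
#' guaranteed nonnegative-definite asymptotically) are clipped to zero; a
#' warning reports the clipped relative spectral mass when it exceeds 1e-8.
#'
#' @param spec A [grf_spec()] object.
#' @return An `ny` x `nx` numeric matrix (rows index y, columns x) with
#'   marginal mean approximately 0 and variance approximately 1.
#' @export
#' @examples
#' f <- sample_grf(grf_spec(64, 64, dx = 0.25, delta = 1.25, seed = 1))
#' round(c(mean(f), stats::var(as.vector(f))), 2)
sample_grf <- function(spec) {
  stopifnot(inherits(spec, "grf_spec"))
  n2x <- 2L * spec$nx
  n2y <- 2L * spec$ny
  # toroidal distances on the padded grid
  tx <- pmin(0:(n2x - 1), n2x - (0:(n2x - 1))) * spec$dx
  ty <- pmin(0:(n2y - 1), n2y - (0:(n2y - 1))) * spec$dx
  r2 <- outer(ty^2, tx^2, `+`)
  covmat <- exp(-r2 / spec$delta^2)
  lam <- Re(stats::fft(covmat))
  neg <- lam < 0
  if (any(neg)) {
    mass <- sum(-lam[neg]) / sum(abs(lam))
    if (mass > 1e-8) {
      warning(sprintf(
        "circulant embedding not nonnegative definite; clipped %.3g relative spectral mass",
        mass))
    }
    lam[neg] <- 0
  }
  z <- with_seed(spec$seed, {
    matrix(complex(real = stats::rnorm(n2x * n2y),
                   imaginary = stats::rnorm(n2x * n2y)), n2y, n2x)
  })
  f <- Re(stats::fft(sqrt(lam) * z)) / sqrt(n2x * n2y)
  f[seq_len(spec$ny), seq_len(spec$nx), drop = FALSE]
}

new_diffusion_field <- function(D, fibrotic, dialect, spec, dx) {
  structure(list(D = D, fibrotic = fibrotic, dialect = dialect, spec = spec,
                 nx = ncol(D), ny = nrow(D), dx = dx),
            class = "diffusion_field")
}

#' Map a raw Gaussian field to a diffusion field
#'
#' The raw field `G` is offset by 2 and multiplied by 0.05, so raw values of
#' -1, 0 and +1 map to diffusion coefficients of 0.05, 0.1 and 0.15
#' mm^2/ms. Values above 0.2 mm^2/ms are capped at 0.2. Nodes whose pre-cap
#' value falls strictly below 0.05 mm^2/ms are designated fibrotic: their
#' diffusion coefficient is set to 0.05 mm^2/ms and the tissue solver treats
#' them as coupled but inexcitable.
#'
#' @param raw Numeric matrix, a raw GRF sample.
#' @param spec The [grf_spec()] the sample came from (provenance), or `NULL`.
#' @param dx Lattice spacing in mm (taken from `spec` when provided).
#' @return A `diffusion_field` object with fields `D` (mm^2/ms), `fibrotic`
#'   (logical mask), `dialect = "smooth"` and `spec`.
#' @export
grf_to_diffusion <- function(raw, spec = NULL, dx = if (is.null(spec)) 0.25 else spec$dx) {
  stopifnot(is.matrix(raw), all(is.finite(raw)))
  pre <- 0.05 * (raw + 2)
  fib <- pre < 0.05
  D <- pmin(pmax(pre, 0.05), 0.2)
  new_diffusion_field(D, fib, "smooth", spec, dx)
}

#' Abrupt (binary) copy of a smooth diffusion field
#'
#' Keeps the fibrotic regions at 0.05 mm^2/ms and sets the diffusion
#' coefficient everywhere else to 0.2 mm^2/ms, producing a field with only
#' two values and an abrupt transition, for comparison against the smooth
#' parent. The fibrotic mask is unchanged.
#'
#' @param field A smooth `diffusion_field`.
#' @return A `diffusion_field` with `dialect = "binary"`.
#' @export
binarize <- function(field) {
  stopifnot(inherits(field, "diffusion_field"))
  if (field$dialect != "smooth") {
    stop("binarize() expects a smooth field; got dialect '", field$dialect, "'")
  }
  D <- matrix(0.2, field$ny, field$nx)
  D[field$fibrotic] <- 0.05
  new_diffusion_field(D, field$fibrotic, "binary", field$spec, field$dx)
}

#' Fraction of fibrotic nodes in a field
#'
#' @param field A `diffusion_field`.
#' @return Proportion of nodes flagged fibrotic, in `[0, 1]`.
#' @export
fibrotic_fraction <- function(field) {
  stopifnot(inherits(field, "diffusion_field"))
  mean(field$fibrotic)
}

#' Uniform diffusion field
#'
#' Homogeneous, non-fibrotic field used for baseline simulations.
#'
#' @param nx,ny Grid points.
#' @param dx Lattice spacing, mm.
#' @param D Diffusion coefficient, mm^2/ms.
#' @return A `diffusion_field` with `dialect = "uniform"`.
#' @export
uniform_diffusion_field <- function(nx, ny, dx = 0.25, D = 0.2) {
  new_diffusion_field(matrix(D, ny, nx), matrix(FALSE, ny, nx), "uniform",
                      NULL, dx)
}

#' Generate the study ensemble of diffusion fields
#'
#' Draws `n_samples` smooth diffusion fields at each correlation length, plus
#' their binary copies. Each sample uses the derived seed
#' `base_seed + 1000 * delta_index + sample_index`, recorded in provenance,
#' so the ensemble is reproducible from `base_seed` alone.
#'
#' @param deltas Correlation lengths, mm.
#' @param n_samples Samples per length scale.
#' @param base_seed Integer base seed.
#' @param nx,ny,dx Grid definition.
#' @return A list with `fields` (nested list `fields[[delta]][[sample]]`
#'   holding `smooth` and `binary` fields) and `manifest` (data frame of
#'   delta, sample, seed and fibrotic fraction per field).
#' @export
generate_study_ensemble <- function(deltas = c(1.25, 2.5, 5, 10),
                                    n_samples = 20, base_seed = 1,
                                    nx = 400, ny = 400, dx = 0.25) {
  stopifnot(n_samples >= 1)
  seeds <- outer(seq_along(deltas) * 1000L, seq_len(n_samples), `+`) + base_seed
  if (anyDuplicated(seeds)) stop("duplicate derived seeds in ensemble")
  fields <- vector("list", length(deltas))
  names(fields) <- as.character(deltas)
  manifest <- vector("list", length(deltas) * n_samples)
  k <- 0
  for (di in seq_along(deltas)) {
    fields[[di]] <- vector("list", n_samples)
    for (si in seq_len(n_samples)) {
      spec <- grf_spec(nx, ny, dx, deltas[di], seeds[di, si])
      smooth <- grf_to_diffusion(sample_grf(spec), spec)
      fields[[di]][[si]] <- list(smooth = smooth, binary = binarize(smooth))
      k <- k + 1
      manifest[[k]] <- data.frame(delta = deltas[di], sample = si,
                                  seed = seeds[di, si],
                                  fraction = fibrotic_fraction(smooth))
    }
  }
  list(fields = fields, manifest = do.call(rbind, manifest))
}

#' @export
print.diffusion_field <- function(x, ...) {
  cat(sprintf("diffusion_field: %d x %d nodes (%.1f x %.1f mm), dialect '%s'\n",
              x$nx, x$ny, x$nx * x$dx, x$ny * x$dx, x$dialect))
  cat(sprintf("  D in [%.3g, %.3g] mm^2/ms; fibrotic fraction %.3f\n",
              min(x$D), max(x$D), fibrotic_fraction(x)))
  if (!is.null(x$spec)) {
    cat(sprintf("  GRF: delta = %g mm, seed = %d\n", x$spec$delta, x$spec$seed))
  }
  invisible(x)
}

#' @export
plot.diffusion_field <- function(x, ...) {
  xs <- (seq_len(x$nx) - 0.5) * x$dx
  ys <- (seq_len(x$ny) - 0.5) * x$dx
  graphics::image(xs, ys, t(x$D), xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("D (mm^2/ms), dialect %s", x$dialect),
                  useRaster = TRUE, ...)
  invisible(x)
}
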