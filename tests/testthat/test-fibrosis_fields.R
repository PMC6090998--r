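test_that("raw field values map to the prescribed diffusion coefficients", {
  raw <- matrix(c(-1, 0, 1, 5, -2.5, 0.3), 2, 3)
  f <- grf_to_diffusion(raw)
  expect_equal(f$D[1, 1], 0.05)
  expect_equal(f$D[2, 1], 0.1)
  expect_equal(f$D[1, 2], 0.15)
  expect_equal(f$D[2, 2], 0.2)   # capped
  expect_false(f$fibrotic[2, 2]) # cap is not fibrosis
  expect_equal(f$D[1, 3], 0.05)
  expect_true(f$fibrotic[1, 3])  # below threshold
  expect_false(f$fibrotic[1, 1]) # exactly 0.05 pre-cap: strict threshold
  expect_equal(f$dialect, "smooth")
})

test_that("mapped fields satisfy the bound/mask invariants for random input", {
  for (seed in 1:5) {
    raw <- with(list(), { set.seed(seed); matrix(rnorm(900, sd = 2), 30, 30) })
    f <- grf_to_diffusion(raw)
    expect_true(all(f$D >= 0.05 & f$D <= 0.2))
    expect_identical(unname(f$fibrotic), unname(0.05 * (raw + 2) < 0.05))
    expect_true(all(f$D[f$fibrotic] == 0.05))
  }
})

test_that("binarize keeps the mask and yields a two-valued field", {
  raw <- matrix(rnorm(400), 20, 20)
  sm <- grf_to_diffusion(raw)
  bi <- binarize(sm)
  expect_identical(bi$fibrotic, sm$fibrotic)
  expect_equal(fibrotic_fraction(bi), fibrotic_fraction(sm))
  expect_setequal(unique(as.vector(bi$D)), c(0.05, 0.2))
  expect_equal(bi$D[!bi$fibrotic][1], 0.2)
  expect_equal(bi$dialect, "binary")
  expect_error(binarize(bi), "smooth")
  all_fib <- grf_to_diffusion(matrix(-3, 4, 4))
  expect_true(all(binarize(all_fib)$D == 0.05))
})

test_that("fibrotic fraction counts mask nodes", {
  f <- grf_to_diffusion(matrix(0, 10, 10))
  expect_equal(fibrotic_fraction(f), 0)
  chk <- matrix(c(-3, 3), 10, 10) # alternating rows below/above threshold
  expect_equal(fibrotic_fraction(grf_to_diffusion(chk)), 0.5)
})

test_that("GRF samples have the specified marginal statistics", {
  for (seed in 1:3) {
    f <- sample_grf(grf_spec(400, 400, 0.25, 1.25, seed = seed))
    expect_gt(mean(f), -0.1); expect_lt(mean(f), 0.1)
    v <- stats::var(as.vector(f))
    expect_gt(v, 0.85); expect_lt(v, 1.15)
  }
})

test_that("pooled GRF values are close to standard normal (KS distance)", {
  f <- sample_grf(grf_spec(400, 400, 0.25, 1.25, seed = 7))
  ks <- suppressWarnings(stats::ks.test(as.vector(f), "pnorm"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("sampling is reproducible per seed and differs across seeds", {
  sp <- grf_spec(64, 64, 0.25, 1.25, seed = 11)
  expect_identical(sample_grf(sp), sample_grf(sp))
  expect_false(identical(sample_grf(sp),
                         sample_grf(grf_spec(64, 64, 0.25, 1.25, seed = 12))))
})

test_that("the spec guards the domain against too-large correlation lengths", {
  expect_error(grf_spec(40, 40, 0.25, delta = 5, seed = 1), "correlation length")
  expect_silent(grf_spec(80, 80, 0.25, delta = 5, seed = 1))
})

test_that("fibrotic-fraction spread grows with correlation length", {
  frac <- function(delta, seed) {
    fibrotic_fraction(grf_to_diffusion(suppressWarnings(
      sample_grf(grf_spec(200, 200, 0.25, delta, seed)))))
  }
  f_small <- vapply(1:25, function(s) frac(1.25, s), numeric(1))
  f_large <- vapply(1:25, function(s) frac(10, s), numeric(1))
  expect_gt(stats::var(f_large), stats::var(f_small))
})

test_that("the diffusion median sits near 0.1 mm^2/ms", {
  f <- grf_to_diffusion(sample_grf(grf_spec(400, 400, 0.25, 2.5, seed = 3)))
  expect_lt(abs(stats::median(f$D) - 0.1), 0.01)
})

test_that("the study ensemble is complete, seeded and reproducible", {
  e1 <- generate_study_ensemble(deltas = c(1.25, 2.5), n_samples = 2,
                                base_seed = 5, nx = 64, ny = 64)
  expect_equal(nrow(e1$manifest), 4)
  expect_false(anyDuplicated(e1$manifest$seed) > 0)
  expect_named(e1$fields, c("1.25", "2.5"))
  expect_length(e1$fields[["1.25"]], 2)
  expect_s3_class(e1$fields[["1.25"]][[1]]$smooth, "diffusion_field")
  expect_equal(e1$fields[["1.25"]][[1]]$binary$dialect, "binary")
  e2 <- generate_study_ensemble(deltas = c(1.25, 2.5), n_samples = 2,
                                base_seed = 5, nx = 64, ny = 64)
  expect_identical(e1$fields[["2.5"]][[2]]$smooth$D,
                   e2$fields[["2.5"]][[2]]$smooth$D)
  single <- generate_study_ensemble(deltas = 1.25, n_samples = 1,
                                    base_seed = 5, nx = 64, ny = 64)
  expect_equal(nrow(single$manifest), 1)
})
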