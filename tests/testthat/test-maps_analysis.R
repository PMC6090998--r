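test_that("crossing detection measures excursions with interpolation and debounce", {
  tr <- rect_trace(10, 110)
  cr <- detect_crossings(tr$t, tr$V)
  expect_equal(nrow(cr), 1)
  expect_equal(cr$t_down - cr$t_up, 100, tolerance = 0.05)

  flat <- rect_trace(0, 0) # never above threshold
  expect_equal(nrow(detect_crossings(flat$t, flat$V)), 0)

  t <- seq(0, 600)
  V <- ifelse((t >= 50 & t < 150) | (t >= 350 & t < 450), 0, -80)
  two <- detect_crossings(t, V)
  expect_equal(nrow(two), 2)
  expect_true(two$t_up[1] < two$t_up[2])

  # a 3 ms blip is discarded as a numerical glitch
  V2 <- ifelse(t >= 200 & t < 203, 0, -80)
  expect_equal(nrow(detect_crossings(t, V2)), 0)

  # excursion still open at the end of the trace
  V3 <- ifelse(t >= 550, 0, -80)
  open <- detect_crossings(t, V3)
  expect_equal(nrow(open), 1)
  expect_true(is.na(open$t_down))
})

test_that("crossing times are linearly interpolated between samples", {
  t <- c(0, 1, 2, 3)
  V <- c(-80, -66, -80, -80) # crosses -73 halfway up and halfway down
  cr <- detect_crossings(t, V, min_width = 0)
  expect_equal(cr$t_up, 0.5)
  expect_equal(cr$t_down, 1.5)
})

test_that("maps attribute crossings to beat windows and exclude fibrotic nodes", {
  # 2 x 2 sheet: node 1 fires in both windows; node 2 only in the first;
  # node 3 is fibrotic but has a passive excursion; node 4 never activates
  t_up <- matrix(NA_real_, 4, 4)
  t_down <- matrix(NA_real_, 4, 4)
  t_up[1:2, 1] <- c(20, 520); t_down[1:2, 1] <- c(320, 820)
  t_up[1, 2] <- 30; t_down[1, 2] <- 330
  t_up[1, 3] <- 25; t_down[1, 3] <- 75
  fib <- matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2)
  rec <- fake_recording(t_up, t_down, 2, 2, fibrotic = fib)
  maps <- build_maps(rec, beat_windows = list(c(0, 500), c(500, 1000)))
  b1 <- maps$beats[[1]]
  expect_equal(b1$t_act[1, 1], 20)
  expect_equal(b1$apd[1, 1], 300)
  expect_true(b1$valid[2, 1])
  expect_false(b1$valid[1, 2]) # fibrotic despite excursion
  expect_false(b1$valid[2, 2]) # never activated
  b2 <- maps$beats[[2]]
  expect_equal(b2$t_act[1, 1], 520)
  expect_false(b2$valid[2, 1]) # no second beat at that node
  expect_error(build_maps(rec, beat_windows = list(c(0, 600), c(500, 1000))),
               "overlap")
})

test_that("recovery may complete beyond its beat window", {
  t_up <- matrix(c(480, NA, NA, NA), 1, 4)
  t_down <- matrix(c(780, NA, NA, NA), 1, 4)
  rec <- fake_recording(t_up, t_down, 2, 2)
  maps <- build_maps(rec, beat_windows = list(c(0, 500)))
  expect_equal(maps$beats[[1]]$apd[1, 1], 300)
})

test_that("delay statistics compare common-valid nodes against the baseline", {
  t_act <- matrix(seq(10, 90, length.out = 9), 3, 3)
  t_rec <- t_act + 250
  base <- fake_map(t_act, t_rec)
  expect_equal(delay_stats(base, base)$median_act_delay, 0)
  expect_equal(delay_stats(base, base)$iqr_act_delay, 0)
  shifted <- fake_map(t_act + 30, t_rec + 30)
  ds <- delay_stats(shifted, base)
  expect_equal(ds$median_act_delay, 30)
  expect_equal(ds$iqr_act_delay, 0)
  expect_equal(ds$median_rec_delay, 30)
  expect_false(ds$low_overlap)
  # fewer than half the baseline's valid nodes comparable -> flagged
  sparse_valid <- matrix(FALSE, 3, 3); sparse_valid[1, 1:3] <- TRUE
  sparse <- fake_map(t_act, t_rec, valid = sparse_valid)
  expect_true(delay_stats(sparse, base)$low_overlap)
})

test_that("the skewness coefficient matches the independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(1)
  x <- rexp(500)
  expect_equal(skewness_fp(x), e1071::skewness(x, type = 2), tolerance = 1e-12)
  expect_equal(skewness_fp(c(2, 2, 2, 2)), 0)
})

test_that("APD distributions report direction of skew", {
  set.seed(2)
  sym <- matrix(rnorm(400, 300, 10), 20, 20)
  m_sym <- fake_map(matrix(10, 20, 20), matrix(10, 20, 20) + sym)
  expect_lt(abs(apd_distribution(m_sym)$skewness), 0.3)
  tail_r <- matrix(300 + rexp(400, 1 / 40), 20, 20)
  m_tail <- fake_map(matrix(10, 20, 20), matrix(10, 20, 20) + tail_r)
  expect_gt(apd_distribution(m_tail)$skewness, 0.5)
  expect_equal(unname(apd_distribution(m_sym)$quartiles[2]),
               stats::median(sym))
  empty <- fake_map(matrix(NA_real_, 2, 2), matrix(NA_real_, 2, 2))
  expect_error(apd_distribution(empty), "no valid nodes")
})

test_that("beat counting flags blocked stimuli and sustained re-entry", {
  g_t <- seq(0, 5000, by = 1)
  mk_trace <- function(ups) {
    V <- rep(-80, length(g_t))
    for (u in ups) V[g_t >= u & g_t < u + 80] <- 0
    V
  }
  proto <- fibroscape:::corner_stimulus_protocol(tissue_geometry(20, 20, 0.25),
                                                 onsets = c(0, 400, 800))
  # probe activates for stimuli 1 and 3 only; 20 extra post-protocol beats
  ups <- c(10, 830, seq(1100, 1100 + 19 * 150, by = 150))
  rec <- fake_recording(matrix(NA_real_, 1, 400), matrix(NA_real_, 1, 400),
                        20, 20, probe_t = g_t,
                        probe_V = cbind(mk_trace(ups)),
                        probes = fibroscape:::node_index(15, 15, 20))
  out <- count_beats(rec, proto)
  expect_equal(out$blocked_stimuli, 2L)
  expect_true(out$sustained) # 20 > 15 post-protocol activations
  expect_equal(out$n_beats, length(ups))

  # silence: zero beats, everything blocked, not sustained
  rec0 <- fake_recording(matrix(NA_real_, 1, 400), matrix(NA_real_, 1, 400),
                         20, 20, probe_t = g_t,
                         probe_V = cbind(rep(-80, length(g_t))),
                         probes = fibroscape:::node_index(15, 15, 20))
  out0 <- count_beats(rec0, proto)
  expect_equal(out0$n_beats, 0)
  expect_equal(out0$blocked_stimuli, 1:3)
  expect_false(out0$sustained)

  # a probe inside the stimulus region is rejected
  rec_bad <- rec; rec_bad$probes <- proto$region[1]
  expect_error(count_beats(rec_bad, proto), "stimulus region")
})

test_that("beat counting is invariant to probe order and duplication", {
  g_t <- seq(0, 1500, by = 1)
  V1 <- rep(-80, length(g_t)); V1[g_t >= 20 & g_t < 100] <- 0
  V2 <- rep(-80, length(g_t))
  for (u in c(30, 400, 700)) V2[g_t >= u & g_t < u + 60] <- 0
  proto <- fibroscape:::corner_stimulus_protocol(tissue_geometry(20, 20, 0.25),
                                                 onsets = 0)
  p1 <- fibroscape:::node_index(15, 15, 20)
  p2 <- fibroscape:::node_index(18, 18, 20)
  rec <- fake_recording(matrix(NA_real_, 1, 400), matrix(NA_real_, 1, 400),
                        20, 20, probe_t = g_t, probe_V = cbind(V1, V2),
                        probes = c(p1, p2))
  rec_swapped <- rec
  rec_swapped$probe_V <- cbind(V2, V1)
  rec_swapped$probes <- c(p2, p1)
  rec_dup <- rec
  rec_dup$probe_V <- cbind(V1, V2, V2)
  rec_dup$probes <- c(p1, p2, p2)
  a <- count_beats(rec, proto)
  expect_equal(count_beats(rec_swapped, proto), a)
  expect_equal(count_beats(rec_dup, proto), a)
})

test_that("wavelength is the APD-CV product with positivity checks", {
  expect_equal(wavelength(300, 0.5), 150)
  expect_error(wavelength(0, 0.5), "positive")
  expect_error(wavelength(300, -1), "positive")
  apd_n <- single_cell_apd(cell_parameters("normal"))
  apd_r <- single_cell_apd(cell_parameters("remodelled"))
  cv0 <- 0.5 # equal diffusion for both variants
  expect_lt(wavelength(apd_r, cv0), wavelength(apd_n, cv0))
})

test_that("isochrones are level sets at the requested spacing", {
  # plane wave at 0.5 mm/ms: t = x / 0.5, on a 40 x 40 sheet (10 mm)
  xs <- matrix(rep((1:40 - 0.5) * 0.25, each = 40), 40, 40)
  m <- fake_map(xs / 0.5, xs / 0.5 + 200)
  cont <- isochrone_export(m, interval = 5)
  expect_gt(length(cont), 1)
  levels <- vapply(cont, function(cl) cl$level, numeric(1))
  expect_true(all(diff(sort(unique(levels))) == 5))
  # vertical, equally spaced contours
  mean_x <- vapply(cont, function(cl) mean(cl$x), numeric(1))
  expect_lt(max(vapply(cont, function(cl) diff(range(cl$x)), numeric(1))), 0.26)
  expect_equal(diff(sort(mean_x)), rep(2.5, length(cont) - 1), tolerance = 0.01)
  # empty map -> no contours
  expect_length(isochrone_export(fake_map(matrix(NA_real_, 3, 3),
                                          matrix(NA_real_, 3, 3))), 0)
  # level count bounded by span / interval
  span_map <- fake_map(matrix(seq(0, 250, length.out = 100), 10, 10),
                       matrix(seq(0, 250, length.out = 100), 10, 10) + 100)
  expect_lte(length(unique(vapply(isochrone_export(span_map, 25),
                                  function(cl) cl$level, numeric(1)))), 10)
})
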