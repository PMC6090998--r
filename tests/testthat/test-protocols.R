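test_that("the S1S2 protocol has the prescribed onsets, region and amplitude", {
  g <- tissue_geometry(100, 100, 0.25)
  p <- build_s1s2(g)
  expect_equal(p$events$onset, c(0, 1000, 2000, 2400))
  expect_length(p$region, 100) # (2.5 mm / 0.25 mm)^2 corner block
  expect_true(all(p$events$amplitude == -2000))
  # region is the lower-left block: rows and columns 1..10
  iy <- (p$region - 1) %% 100 + 1
  jx <- (p$region - 1) %/% 100 + 1
  expect_true(all(iy <= 10 & jx <= 10))
})

test_that("decremental onsets follow the decreasing-interval rule with a clamped tail", {
  g <- tissue_geometry(400, 400, 0.25)
  pn <- build_decremental("normal", g)
  expect_equal(pn$events$onset,
               c(0, 450, 875, 1275, 1650, 2000, 2325, 2625, 2900, 3150))
  pr <- build_decremental("remodelled", g)
  expect_equal(diff(pr$events$onset),
               c(300, 275, 250, 225, 200, 175, 150, 150, 150))
  expect_equal(nrow(pr$events), 10)
})

test_that("the decremental pacing disc has a 6.25 mm radius about the centre", {
  g <- tissue_geometry(400, 400, 0.25)
  p <- build_decremental("normal", g)
  centre <- fibroscape:::node_index(200, 200, 400)
  expect_true(centre %in% p$region)
  off <- fibroscape:::node_index(200, 230, 400) # 30 nodes = 7.5 mm away
  expect_false(off %in% p$region)
  # every member lies within 6.25 mm of the domain centre
  iy <- (p$region - 1) %% 400 + 1
  jx <- (p$region - 1) %/% 400 + 1
  r <- sqrt(((iy - 0.5) * 0.25 - 50)^2 + ((jx - 0.5) * 0.25 - 50)^2)
  expect_true(all(r <= 6.25))
})

test_that("stimulus onsets must strictly increase", {
  g <- tissue_geometry(20, 20, 0.25)
  expect_error(fibroscape:::new_protocol(
    "bad", data.frame(onset = c(0, 0), duration = 2, amplitude = -2000),
    1L, g), "increasing")
})

test_that("protocols are deterministic in their inputs", {
  g <- tissue_geometry(120, 120, 0.25)
  expect_identical(build_s1s2(g), build_s1s2(g))
  expect_identical(build_decremental("remodelled", g),
                   build_decremental("remodelled", g))
})

test_that("protocols round-trip through JSON losslessly", {
  g <- tissue_geometry(80, 80, 0.25)
  p <- build_decremental("normal", g)
  q <- protocol_from_json(protocol_to_json(p))
  expect_equal(q$kind, p$kind)
  expect_equal(q$events, p$events)
  expect_identical(q$region, p$region)
  expect_equal(q$geometry$nx, p$geometry$nx)
  expect_equal(q$variant, p$variant)
})

test_that("the spiral state is an Archimedean phase map of the cycle trajectory", {
  g <- tissue_geometry(120, 120, 0.25) # 30 x 30 mm
  pitch <- 10
  init <- build_spiral_state("remodelled", g, pitch = pitch)
  expect_equal(dim(init), c(19L, 120L * 120L))
  V <- matrix(init["V", ], 120, 120)
  # along the +x ray from the centre, V is periodic in r with period = pitch
  centre_row <- 60
  ray <- V[centre_row, 61:120] # r = 0.125, 0.375, ... mm steps of 0.25
  lag <- pitch / 0.25
  # median over pairs: the ray sits half a node off the true centre line, so
  # the azimuthal phase term leaves a small residual that can be large for
  # the rare pair straddling the upstroke
  expect_lt(stats::median(abs(ray[1:(60 - lag)] - ray[(1 + lag):60])), 2)
  # the full trajectory voltage range appears when pitch < domain size
  traj <- cycle_trajectory("remodelled")
  expect_lt(abs(max(V) - max(traj$states["V", ])), 5)
  expect_lt(abs(min(V) - min(traj$states["V", ])), 5)
  # the centre node has a defined state
  expect_true(all(is.finite(init[, fibroscape:::node_index(60, 60, 120)])))
})

test_that("spiral construction rejects a non-positive pitch and rests fibrotic nodes", {
  g <- tissue_geometry(40, 40, 0.25)
  expect_error(build_spiral_state("normal", g, pitch = 0), "pitch")
  raw <- matrix(2, 40, 40); raw[1:5, 1:5] <- -3
  f <- grf_to_diffusion(raw)
  init <- build_spiral_state("remodelled", g, field = f, pitch = 8)
  rest <- initialize_variant(cell_parameters("remodelled"))
  expect_equal(unname(init[, fibroscape:::node_index(2, 2, 40)]), unname(rest))
})
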