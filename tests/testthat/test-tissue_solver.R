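test_that("the adaptive step follows the stimulus / dV/dt / stability rules", {
  expect_equal(choose_dt(D_max = 0.2, dx = 0.25, stimulus_active = TRUE), 0.01)
  expect_equal(choose_dt(D_max = 0.2, dx = 0.25, max_dvdt = 12), 0.01)
  expect_equal(choose_dt(D_max = 0.2, dx = 0.25), 0.078125)
  expect_equal(choose_dt(D_max = 0.05, dx = 0.25), 0.1) # bound 0.3125 not binding
})

test_that("the diffusion stencil conserves total voltage under no-flux boundaries", {
  set.seed(42)
  D <- matrix(runif(1600, 0.05, 0.2), 40, 40)
  V0 <- matrix(rnorm(1600, -60, 25), 40, 40)
  V1 <- fibroscape:::cpp_diffuse_only(D, 0.25, V0, dt = 0.05, n_steps = 1000)
  expect_lt(abs(sum(V1) - sum(V0)) / abs(sum(V0)), 1e-9)
})

test_that("resting tissue stays at rest for 500 ms", {
  f <- uniform_diffusion_field(20, 20, 0.25, 0.2)
  rec <- run_simulation(f, "normal", protocol = NULL, duration = 500,
                        probes = fibroscape:::node_index(10, 10, 20))
  v_rest <- rec$probe_V[1, 1]
  expect_lt(max(abs(rec$probe_V[, 1] - v_rest)), 0.5)
  expect_equal(sum(rec$n_up), 0)
})

test_that("a voltage spike in fully fibrotic tissue decays passively", {
  ny <- 15; nx <- 15
  f <- grf_to_diffusion(matrix(-3, ny, nx)) # everything fibrotic
  expect_equal(fibrotic_fraction(f), 1)
  init <- matrix(crn_initial_state(), ncol = 1)[, rep(1, nx * ny)]
  centre <- fibroscape:::node_index(8, 8, ny)
  init[1, centre] <- 0 # +80 mV spike on one node
  rec <- run_simulation(f, "normal", protocol = NULL, duration = 50,
                        init_state = init, probes = centre,
                        probe_interval = 0.5)
  v <- rec$probe_V[, 1]
  expect_true(all(diff(v) <= 1e-9))         # monotone decay, no regeneration
  expect_lt(v[length(v)], -70)
})

test_that("tissue runs are deterministic", {
  f <- uniform_diffusion_field(20, 20, 0.25, 0.2)
  g <- tissue_geometry(20, 20, 0.25)
  proto <- fibroscape:::corner_stimulus_protocol(g, onsets = 0)
  probe <- fibroscape:::node_index(15, 15, 20)
  r1 <- run_simulation(f, "normal", proto, duration = 40, probes = probe)
  r2 <- run_simulation(f, "normal", proto, duration = 40, probes = probe)
  expect_identical(r1$probe_V, r2$probe_V)
  expect_identical(r1$t_up, r2$t_up)
})

test_that("corner pacing activates the whole sheet with distance-ordered timing", {
  ny <- 40; nx <- 40
  f <- uniform_diffusion_field(nx, ny, 0.25, 0.2)
  g <- tissue_geometry(nx, ny, 0.25)
  proto <- fibroscape:::corner_stimulus_protocol(g, onsets = 0)
  rec <- run_simulation(f, "normal", proto, duration = 60)
  expect_equal(sum(rec$n_up > 0), nx * ny)
  t_act <- matrix(rec$t_up[1, ], ny, nx)
  # activation time increases along the diagonal away from the corner
  diag_t <- t_act[cbind(seq(12, 40, by = 4), seq(12, 40, by = 4))]
  expect_true(all(diff(diag_t) > 0))
})

test_that("an isolating fibrotic wall blocks propagation", {
  # fibrotic tissue is coupled, so the wall must be thick relative to the
  # passive space constant (2.5 mm here), and the far side must be a real
  # diffusive sink — a narrow sealed-end strip can still regenerate from
  # the boundary-reflected depolarization
  ny <- 30; nx <- 60
  raw <- matrix(2, ny, nx)
  raw[, 15:24] <- -3 # 2.5 mm fibrotic wall across the full height
  f <- grf_to_diffusion(raw)
  g <- tissue_geometry(nx, ny, 0.25)
  proto <- fibroscape:::corner_stimulus_protocol(g, onsets = 0)
  rec <- run_simulation(f, "normal", proto, duration = 200)
  left <- matrix(rec$n_up, ny, nx)[, 1:14]
  right_excitable <- matrix(rec$n_up, ny, nx)[, 27:60]
  expect_true(all(left > 0))
  expect_equal(sum(right_excitable), 0)
})

test_that("a fine step beyond the stability bound is rejected before stepping", {
  f <- uniform_diffusion_field(10, 10, 0.05, 0.2) # bound = 0.003125 ms
  expect_error(run_simulation(f, "normal", protocol = NULL, duration = 1),
               "stability")
})

test_that("a protocol extending beyond the run duration is rejected", {
  f <- uniform_diffusion_field(10, 10, 0.25, 0.2)
  g <- tissue_geometry(10, 10, 0.25)
  proto <- fibroscape:::corner_stimulus_protocol(g, onsets = c(0, 500))
  expect_error(run_simulation(f, "normal", proto, duration = 300), "beyond")
})

test_that("plane-wave measurement rejects ill-posed column choices", {
  expect_error(plane_wave_cv("normal", 0.2, x1 = 50, x2 = 50))
  expect_error(plane_wave_cv("normal", 0.2, x1 = 40, x2 = 60), "25 mm")
  expect_error(plane_wave_cv("normal", 0.2, x1 = 10, x2 = 70), "25 mm")
})

test_that("plane-wave conduction velocity converges under time-step refinement", {
  cv1 <- plane_wave_cv("normal", 0.2, nx = 320, ny = 8, x1 = 27, x2 = 53)
  cv2 <- plane_wave_cv("normal", 0.2, nx = 320, ny = 8, x1 = 27, x2 = 53,
                       dt_fine = 0.005, dt_max = 0.05)
  expect_lt(abs(cv2 - cv1) / cv1, 0.01)
})

test_that("fibrotic voltage excursions are smaller than in adjacent excitable tissue", {
  ny <- 30; nx <- 30
  raw <- matrix(2, ny, nx)
  raw[10:21, 10:21] <- -3 # large central fibrotic patch
  f <- grf_to_diffusion(raw)
  g <- tissue_geometry(nx, ny, 0.25)
  proto <- fibroscape:::corner_stimulus_protocol(g, onsets = 0)
  inside <- fibroscape:::node_index(15, 15, ny)  # patch centre
  outside <- fibroscape:::node_index(25, 25, ny) # excitable far corner
  rec <- run_simulation(f, "normal", proto, duration = 150,
                        probes = c(inside, outside))
  excursion <- apply(rec$probe_V, 2, function(v) max(v) - v[1])
  expect_lt(excursion[1], excursion[2])
})
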