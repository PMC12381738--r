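# Engine-level tests on toy configurations; full inversion studies live in
# test-acceptance.R.

test_that("source-scale projection recovers exact complex scalings", {
  p <- complex(real = c(1, 0), imaginary = c(0, 1))   # [1, i]
  expect_equal(estimate_source_scale(p, p), 1 + 0i)
  expect_equal(estimate_source_scale(p, 2i * p), 2i)
  # hand-evaluated projection: ((1)(2) + (-i)(0)) / (1 + 1) = 1
  expect_equal(estimate_source_scale(p, c(2 + 0i, 0i)), 1 + 0i)
  expect_error(estimate_source_scale(c(0i, 0i), p), "zero")
  expect_error(estimate_source_scale(p, c(1i)), "lengths")
})

test_that("the projection scale minimizes the misfit over the complex plane", {
  set.seed(71)
  p <- complex(real = rnorm(20), imaginary = rnorm(20))
  p_obs <- complex(real = rnorm(20), imaginary = rnorm(20))
  gam <- estimate_source_scale(p, p_obs)
  E <- function(g) 0.5 * sum(Mod(g * p - p_obs)^2)
  E_opt <- E(gam)
  # dense grid search over a window around the optimum
  gr <- seq(-2, 2, length.out = 81)
  E_grid <- outer(gr, gr, Vectorize(function(a, b) E(complex(real = a, imaginary = b))))
  expect_gte(min(E_grid), E_opt - 1e-12)
  # and cost at gamma=1 is never below the optimum
  expect_gte(E(1 + 0i), E_opt)
})

test_that("waveform misfit matches its definition", {
  expect_equal(fwi_cost(matrix(1 + 0i), matrix(0i)), 0.5)
  set.seed(72)
  p <- matrix(complex(real = rnorm(12), imaginary = rnorm(12)), 3)
  q <- matrix(complex(real = rnorm(12), imaginary = rnorm(12)), 3)
  brute <- 0
  for (i in 1:3) for (j in 1:4) brute <- brute + 0.5 * Mod(p[i, j] - q[i, j])^2
  expect_equal(fwi_cost(p, q), brute)
  expect_equal(fwi_cost(p, p), 0)
  expect_error(fwi_cost(p, q[, 1:2]), "shapes")
})

test_that("adjoint-state gradient matches finite differences of the misfit", {
  # 16x16 toy, 4 elements, 1 transmit, direct-solve oracle throughout
  g <- ust_grid(c(16, 16), 2e-3)
  omega <- 2 * pi * 120e3
  st <- born_settings(pad_slowness = 1 / 1500, method = "direct", pad_width = 6)
  spec <- ring_array(0.012, n_rows = 1, n_elements_per_row = 4, center = c(0, 0))
  K <- sampling_operator(spec, g)
  tm <- transmit_set(spec, 0L)
  cvals <- smooth_speed_map(c(16, 16), 1470, 1530, sigma = 1.5, seed = 73)
  s <- slowness_from_speed(g, cvals)
  truth <- slowness_from_speed(g, cvals + 10)
  p_obs <- forward_model(truth, omega, tm, K, st)$p

  fm <- forward_model(s, omega, tm, K, st)
  grad <- fwi_gradient(s, omega, fm$u, fm$p, p_obs, K, st)
  fd <- array(0, dim = g$shape)
  step <- 1e-7
  for (j in seq_len(256)) {
    sp <- s$values; sp[j] <- sp[j] * (1 + step)
    sm <- s$values; sm[j] <- sm[j] * (1 - step)
    Ep <- fwi_cost(forward_model(slowness_field(g, sp), omega, tm, K, st)$p, p_obs)
    Em <- fwi_cost(forward_model(slowness_field(g, sm), omega, tm, K, st)$p, p_obs)
    fd[j] <- (Ep - Em) / (2 * step * s$values[j])
  }
  rel <- abs(grad - fd) / pmax(abs(fd), 1e-3 * max(abs(fd)))
  expect_lt(max(rel), 1e-3)
})

test_that("zero data residual gives a zero gradient", {
  g <- ust_grid(c(16, 16), 2e-3)
  omega <- 2 * pi * 100e3
  st <- born_settings(pad_slowness = 1 / 1500, pad_width = 8)
  spec <- ring_array(0.012, n_rows = 1, n_elements_per_row = 6, center = c(0, 0))
  K <- sampling_operator(spec, g)
  tm <- transmit_set(spec, c(0L, 3L))
  s <- slowness_from_speed(g, 1500)
  fm <- forward_model(s, omega, tm, K, st)
  grad <- fwi_gradient(s, omega, fm$u, fm$p, fm$p, K, st)
  expect_equal(max(abs(grad)), 0)
})

test_that("gradient of a mirror-symmetric problem is mirror-symmetric", {
  g <- ust_grid(c(24, 24), 2e-3)
  omega <- 2 * pi * 100e3
  st <- born_settings(pad_slowness = 1 / 1500, pad_width = 8, method = "direct")
  # receivers and source symmetric about the x axis; medium symmetric too
  spec <- ring_array(0.018, n_rows = 1, n_elements_per_row = 8, center = c(0, 0))
  K <- sampling_operator(spec, g)
  tm <- transmit_set(spec, 0L)            # source at angle 0: on the axis
  c0 <- array(1500, g$shape)
  x <- grid_coords(g, 1); y <- grid_coords(g, 2)
  blob <- outer(exp(-x^2 / 1e-4), exp(-y^2 / 1e-4))
  s <- slowness_from_speed(g, c0 + 40 * blob)   # even in y
  truth <- slowness_from_speed(g, c0 + 55 * blob)
  p_obs <- forward_model(truth, omega, tm, K, st)$p
  fm <- forward_model(s, omega, tm, K, st)
  grad <- fwi_gradient(s, omega, fm$u, fm$p, p_obs, K, st)
  flipped <- grad[, rev(seq_len(24))]
  expect_lt(max(abs(grad - flipped)) / max(abs(grad)), 1e-6)
})

test_that("NCG takes steepest descent first and when gradients repeat", {
  # quadratic toy cost F(s) = 1/2 (s - s*)^T H (s - s*) exercised through
  # ncg_step's interface
  g <- ust_grid(c(8, 8), 1e-3)
  target <- array(1 / 1500, c(8, 8))
  H <- 2
  cost_of <- function(sf) list(cost = 0.5 * H * sum((sf$values - target)^2),
                               forward = NULL)
  cfg <- fwi_config(frequencies = 1e5, iterations_per_frequency = 1,
                    max_dc_first = 10)
  s0 <- slowness_from_speed(g, 1520)
  state <- list(s = s0, g_prev = NULL, d_prev = NULL, alpha_prev = NULL)
  grad <- H * (s0$values - target)
  st1 <- ncg_step(state, grad, cost_of, cost_of(s0)$cost, cfg)
  expect_equal(st1$d_prev, -grad)              # restart: steepest descent
  expect_true(st1$accepted)
  expect_lt(st1$cost, cost_of(s0)$cost)

  # identical consecutive gradients: PR numerator vanishes, beta = 0
  st2 <- st1
  st2$d_prev <- array(0.5, c(8, 8))            # pretend a previous direction
  st3 <- ncg_step(st2, st2$g_prev, cost_of, st2$cost, cfg)
  expect_equal(st3$d_prev, -st2$g_prev)
})

test_that("NCG with generous line search minimizes a quadratic in few steps", {
  g <- ust_grid(c(8, 8), 1e-3)
  target <- array(1 / 1500, c(8, 8))
  cost_of <- function(sf) list(cost = 0.5 * sum((sf$values - target)^2),
                               forward = NULL)
  cfg <- fwi_config(frequencies = 1e5, iterations_per_frequency = 1,
                    max_dc_first = 40, max_backtracks = 60,
                    backtrack_shrink = 0.7)
  state <- list(s = slowness_from_speed(g, 1530), g_prev = NULL,
                d_prev = NULL, alpha_prev = NULL)
  for (k in 1:35) {
    grad <- state$s$values - target
    state <- ncg_step(state, grad, cost_of, cost_of(state$s)$cost, cfg)
    if (!state$accepted) break
  }
  expect_lt(cost_of(state$s)$cost, 1e-8 * 0.5 * sum((1 / 1530 - target)^2))
})

test_that("FWI on self-consistent data is a fixed point of the inversion", {
  toy <- toy_ring_2d(n = 32, h = 2.5e-3, radius = 0.03, nel = 12)
  tm <- transmit_set(toy$spec, c(0L, 4L, 8L))
  st <- born_settings(tolerance = 1e-5, pad_slowness = 1 / 1500, pad_width = 8)
  s0 <- slowness_from_speed(toy$grid, 1500)
  data <- simulate_observed_data(s0, toy$spec, tm, c(80e3, 120e3), st)
  cfg <- fwi_config(frequencies = c(80e3, 120e3), iterations_per_frequency = 2,
                    settings = st)
  res <- run_fwi(data, cfg, toy$grid)
  expect_lt(max(abs(res$sound_speed - 1500)) / 1500, 1e-6)
  expect_true(all(res$history$cost < 1e-20))
})

test_that("per-frequency cost never increases across accepted iterations", {
  toy <- toy_ring_2d(n = 32, h = 2.5e-3, radius = 0.03, nel = 16)
  tm <- transmit_set(toy$spec, seq(0L, 15L, by = 4L))
  st <- born_settings(tolerance = 1e-4, pad_slowness = 1 / 1500, pad_width = 8)
  set.seed(77)
  ctrue <- 1500 + 25 * ringfwi:::gaussian_smooth(array(rnorm(1024), c(32, 32)), 3)
  truth <- slowness_from_speed(toy$grid, ctrue)
  data <- simulate_observed_data(truth, toy$spec, tm, c(80e3, 120e3), st)
  cfg <- fwi_config(frequencies = c(80e3, 120e3), iterations_per_frequency = 3,
                    settings = st)
  res <- run_fwi(data, cfg, toy$grid)
  for (f in unique(res$history$frequency_hz)) {
    h <- res$history[res$history$frequency_hz == f, ]
    expect_true(all(diff(h$cost) <= 1e-12))
  }
  # and the inversion actually improved the model
  ev <- evaluate_reconstruction(res, ctrue)
  ev0 <- evaluate_reconstruction(array(1500 + 1e-9, dim(ctrue)) +
                                   array(rnorm(1024, sd = 1e-9), dim(ctrue)),
                                 ctrue)
  expect_lt(ev$rmse, ev0$rmse)
})

test_that("slicewise slices agree with each other for z-invariant media", {
  # extruded (z-invariant) truth, two rows symmetric about the mid-plane:
  # each row sees identical data, so the reconstructed slices must match
  g3 <- ust_grid(c(24, 24, 8), 3e-3)
  spec <- ring_array(0.025, n_rows = 2, n_elements_per_row = 12,
                     row_pitch = 6e-3)
  tm <- transmit_set(spec, c(0L, 4L, 8L))
  st <- born_settings(tolerance = 1e-4, pad_slowness = 1 / 1500, pad_width = 8)
  c2d <- smooth_speed_map(c(24, 24), 1470, 1530, seed = 79)
  truth <- slowness_from_speed(g3, array(rep(c2d, 8), dim = g3$shape))
  data <- simulate_observed_data(truth, spec, tm, 80e3, st)
  cfg <- fwi_config(frequencies = 80e3, iterations_per_frequency = 2,
                    settings = st)
  res <- run_slicewise_fwi(data, cfg, g3)
  expect_length(res$slices, 2)
  expect_lt(max(abs(res$slices[[1]] - res$slices[[2]])) /
              max(abs(res$slices[[1]] - 1500)), 0.05)
})

test_that("forward-model solver failures carry the transmit index", {
  toy <- toy_ring_2d(n = 32, h = 2.5e-3, radius = 0.03, nel = 8)
  s <- slowness_from_speed(toy$grid, 1500)
  bad <- born_settings(pad_slowness = 1 / 1500, max_iterations = 2L)
  expect_error(
    forward_model(s, 2 * pi * 100e3, transmit_set(toy$spec, 3L), toy$K, bad),
    "transmit 3.*did not converge"
  )
})

test_that("slicewise inversion of a single-row array is one 2D reconstruction", {
  g3 <- ust_grid(c(24, 24, 8), 3e-3)
  spec <- ring_array(0.025, n_rows = 1, n_elements_per_row = 12)
  tm <- transmit_set(spec, c(0L, 6L))
  st <- born_settings(tolerance = 1e-4, pad_slowness = 1 / 1500, pad_width = 8)
  g2 <- ust_grid(c(24, 24), 3e-3)
  s0 <- slowness_from_speed(g2, 1500)
  data2 <- simulate_observed_data(s0, ring_array(0.025, n_rows = 1,
                                                 n_elements_per_row = 12,
                                                 center = c(0, 0)),
                                  tm, 80e3, st)
  # re-tag the 2D data as coming from the 3D single-row array
  data3 <- frequency_data(data2$frequencies, data2$matrices, spec, tm)
  cfg <- fwi_config(frequencies = 80e3, iterations_per_frequency = 1,
                    settings = st)
  res <- run_slicewise_fwi(data3, cfg, g3)
  expect_length(res$slices, 1)
  # every z level carries the same single slice
  for (k in 1:8) expect_equal(res$sound_speed[, , k], res$slices[[1]])
})
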