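test_that("receive delay law matches the closed form", {
  expect_equal(receive_delay(0, 0, 30e-3, 1540), 2 * 30e-3 / 1540)
  expect_equal(receive_delay(0, 0, 30e-3, 1540), 38.96e-6, tolerance = 1e-3)
  # degenerate depth limit: tau -> tau_F + |x - x_c| / c
  expect_equal(receive_delay(2e-3, 0, 1e-12, 1540), 2e-3 / 1540,
               tolerance = 1e-9)
  # transmit delay is purely additive
  expect_equal(receive_delay(3e-3, 1e-3, 25e-3, 1540, tau_F = 1e-6) -
                 receive_delay(3e-3, 1e-3, 25e-3, 1540), 1e-6)
  expect_error(receive_delay(0, 0, -1e-3, 1540), "invalid depth")
})

test_that("coherence factor matches hand-evaluated cases and its bounds", {
  expect_equal(coherence_factor(rep(2.5, 6)), 1)
  expect_equal(coherence_factor(c(1, -1)), 0)
  expect_equal(coherence_factor(c(1, 1, 0, 0)), 0.5)
  expect_equal(coherence_factor(0), 0) # zero-energy convention
  expect_equal(coherence_factor(c(NA, 3, 3)), 1) # NA = outside subaperture
  expect_error(coherence_factor(numeric(0)), "at least one")

  set.seed(11)
  for (i in 1:200) {
    s <- stats::rnorm(sample(1:32, 1))
    cf <- coherence_factor(s)
    expect_gte(cf, 0)
    expect_lte(cf, 1)
    # scale invariance
    g <- stats::runif(1, 0.01, 100) * sample(c(-1, 1), 1)
    expect_equal(coherence_factor(g * s), cf, tolerance = 1e-9)
  }
})

test_that("focused DAS matches an independently coded naive beamformer", {
  set.seed(19)
  for (rep in 1:4) {
    ne <- sample(4:8, 1)
    arr <- make_array(n_elements = ne, pitch = 0.4e-3)
    nk <- sample(3:10, 1)
    sc <- point_scene(stats::runif(nk, -1.5e-3, 1.5e-3),
                      stats::runif(nk, 8e-3, 20e-3),
                      stats::runif(nk, 0.5, 2))
    tx <- focused_delays(arr, c(0, 15e-3))
    rf <- simulate_rf(arr, tx, make_pulse(), sc)
    bf <- das_focused(rf, f_number = 1.1, z_range = c(6e-3, 22e-3),
                      return_samples = TRUE)
    orc <- oracle_das(rf$data, rf$fs, rf$t0, arr$element_x, arr$element_x,
                      bf$y$z_grid, tx$delays, arr$c, 1.1)
    expect_lt(max(abs(bf$y$values - orc$y)) / max(abs(orc$y)), 1e-6)
    expect_lt(max(abs(bf$cf_map$values - orc$cf)), 1e-6)
    # CF recomputable from the exposed subaperture samples
    iz <- sample(length(bf$y$z_grid), 1)
    ix <- sample(ne, 1)
    expect_equal(coherence_factor(bf$samples[iz, ix, ]),
                 bf$cf_map$values[iz, ix], tolerance = 1e-9)
  }
})

test_that("focused DAS localizes a scatterer at the transmit focus", {
  arr <- make_array(n_elements = 8, pitch = 0.4e-3)
  focus <- c(0, 12e-3)
  tx <- focused_delays(arr, focus)
  sc <- point_scene(focus[1], focus[2])
  rf <- simulate_rf(arr, tx, make_pulse(), sc)
  bf <- das_focused(rf, z_range = c(8e-3, 16e-3))
  pk <- arg_max_image(beamformed_image(abs(bf$y$values), bf$y$x_grid,
                                       bf$y$z_grid, "envelope"))
  dz <- bf$y$z_grid[2] - bf$y$z_grid[1]
  expect_lte(abs(pk["x"] - focus[1]), arr$pitch + 1e-12)
  expect_lte(abs(pk["z"] - focus[2]), dz + 1e-12)
})

test_that("DAS is linear and zero-preserving", {
  arr <- make_array(n_elements = 6, pitch = 0.5e-3)
  tx <- focused_delays(arr, c(0, 12e-3))
  sc <- point_scene(0, 12e-3)
  rf <- simulate_rf(arr, tx, make_pulse(), sc)
  bf <- das_focused(rf, z_range = c(9e-3, 15e-3))
  rf0 <- rf
  rf0$data <- rf0$data * 0
  expect_true(all(das_focused(rf0, z_range = c(9e-3, 15e-3))$y$values == 0))
  rfg <- rf
  rfg$data <- rfg$data * 3.7
  bfg <- das_focused(rfg, z_range = c(9e-3, 15e-3))
  expect_equal(bfg$y$values, 3.7 * bf$y$values, tolerance = 1e-12)
  expect_error(das_focused(rf, f_number = 0), "f_number")
})

test_that("plane-wave DAS localizes a point target at angle 0", {
  arr <- make_array(n_elements = 16, pitch = 0.3048e-3)
  sc <- point_scene(0.5e-3, 14e-3)
  rf <- simulate_rf(arr, plane_wave_delays(arr, 0), make_pulse(), sc)
  bf <- das_plane_wave(rf, z_range = c(10e-3, 18e-3))
  pk <- arg_max_image(beamformed_image(abs(bf$y$values), bf$y$x_grid,
                                       bf$y$z_grid, "envelope"))
  dz <- bf$y$z_grid[2] - bf$y$z_grid[1]
  expect_lte(abs(pk["x"] - 0.5e-3), arr$pitch + 1e-12)
  expect_lte(abs(pk["z"] - 14e-3), dz + 1e-12)
})

test_that("CF weighting attenuates but never amplifies", {
  arr <- make_array(n_elements = 8, pitch = 0.4e-3)
  tx <- focused_delays(arr, c(0, 12e-3))
  sc <- point_scene(c(0, 0.8e-3), c(11e-3, 13e-3), c(1, 0.7))
  rf <- simulate_rf(arr, tx, make_pulse(), sc)
  bf <- das_focused(rf, z_range = c(9e-3, 15e-3))
  ycf <- apply_cf(bf$y, bf$cf_map)
  expect_true(all(abs(ycf$values) <= abs(bf$y$values) + 1e-15))
  # identity and annihilation
  ones <- beamformed_image(matrix(1, nrow(bf$y$values), ncol(bf$y$values)),
                           bf$y$x_grid, bf$y$z_grid, "cf_map")
  expect_equal(apply_cf(bf$y, ones)$values, bf$y$values)
  zeros <- beamformed_image(matrix(0, nrow(bf$y$values), ncol(bf$y$values)),
                            bf$y$x_grid, bf$y$z_grid, "cf_map")
  expect_true(all(apply_cf(bf$y, zeros)$values == 0))
  # grid mismatch
  other <- beamformed_image(bf$cf_map$values[-1, , drop = FALSE],
                            bf$y$x_grid, bf$y$z_grid[-1], "cf_map")
  expect_error(apply_cf(bf$y, other), "grid mismatch")
})

test_that("coherent compounding sums RF images and reduces sidelobes", {
  arr <- make_array(n_elements = 32, pitch = 0.3048e-3)
  sc <- point_scene(0, 12e-3)
  angles <- seq(-18, 18, by = 6) * pi / 180
  imgs <- lapply(angles, function(a) {
    rf <- simulate_rf(arr, plane_wave_delays(arr, a), make_pulse(), sc)
    das_plane_wave(rf, z_range = c(9e-3, 15e-3))$y
  })
  one <- compound(imgs[4])
  expect_equal(one$values, imgs[[4]]$values)
  three <- compound(list(imgs[[4]], imgs[[4]], imgs[[4]]))
  expect_equal(three$values, 3 * imgs[[4]]$values)

  psl <- function(img) {
    env <- envelope(img)
    prof <- lateral_profile(env, 12e-3)
    db <- 20 * log10(pmax(prof$values / max(prof$values), 1e-30))
    main <- abs(prof$x - prof$x[which.max(db)]) <= 1e-3
    max(db[!main])
  }
  expect_lt(psl(compound(imgs)), min(vapply(imgs, psl, numeric(1))))
})

test_that("envelope detection recovers the amplitude of a windowed tone", {
  n <- 512
  z <- seq_len(n)
  a <- 1.8
  v <- matrix(a * sin(2 * pi * 0.1 * z), n, 1)
  img <- beamformed_image(v, 0, z * 1e-4, "y")
  env <- envelope(img)
  expect_true(all(env$values >= 0))
  interior <- env$values[100:400, 1]
  expect_lt(max(abs(interior - a)) / a, 0.02)
  # zero in, zero out
  z0 <- beamformed_image(matrix(0, 16, 2), c(0, 1e-3), (1:16) * 1e-4, "y")
  expect_true(all(envelope(z0)$values == 0))
})

test_that("log compression is max-normalized with the right scaling", {
  v <- matrix(c(1, 0.1, 0.01, 1e-9), 4, 1)
  env <- beamformed_image(v, 0, (1:4) * 1e-4, "envelope")
  db <- log_compress(env)
  expect_equal(db$values[1, 1], 0)
  expect_equal(db$values[2, 1], -20)
  expect_equal(db$values[4, 1], -60) # clipped at the floor
  int <- beamformed_image(v, 0, (1:4) * 1e-4, "intensity")
  dbi <- log_compress(int)
  expect_equal(dbi$values[3, 1], -20) # 10 log10 for intensity
  z0 <- beamformed_image(matrix(0, 4, 1), 0, (1:4) * 1e-4, "envelope")
  expect_error(log_compress(z0), "all-zero")
})
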