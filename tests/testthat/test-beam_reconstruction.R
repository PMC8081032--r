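mk_img <- function(v, kind = "y") {
  v <- as.matrix(v)
  beamformed_image(v, (seq_len(ncol(v)) - 1) * 1e-3,
                   seq_len(nrow(v)) * 1e-4, kind)
}

test_that("the sliding axial integral matches hand-evaluated cases", {
  # constant |y| = 1, L = 8, dz = 1 -> 8 away from the deep edge
  img <- mk_img(matrix(1, 32, 3))
  I <- intensity_field(img, 8, dz = 1)
  expect_true(all(I$values[1:24, ] == 8))
  expect_equal(I$values[32, 1], 1) # zero-padded deep edge
  # L = 1 -> dz * y^2
  set.seed(4)
  v <- matrix(stats::rnorm(60), 20, 3)
  expect_equal(intensity_field(mk_img(v), 1, dz = 0.5)$values, 0.5 * v^2)
  # column (1, 2, 0, ...), L = 2, dz = 0.5 -> 0.5 * (1 + 4) = 2.5
  col <- matrix(c(1, 2, rep(0, 8)), 10, 1)
  expect_equal(intensity_field(mk_img(col), 2, dz = 0.5)$values[1, 1], 2.5)
  expect_error(intensity_field(mk_img(col), 11), "exceeds")
  expect_true(all(intensity_field(mk_img(v), 4)$values >= 0))
})

test_that("B-mode smoothing is a reflection-padded moving average", {
  # kernel-in-pixels: wavelength 0.4 mm with dz = 0.1 mm and dx = 1 mm
  # gives 5.5 x 7 wavelengths -> 21 x 3 px (nearest odd)
  wl <- 4e-4
  env <- mk_img(matrix(2.5, 40, 9), "envelope")
  sm <- smooth_bmode(env, c(5.5, 7), wl)
  expect_equal(sm$values, env$values, tolerance = 1e-12) # constant unchanged
  # impulse -> plateau of 1/(k_ax * k_lat) over the kernel footprint
  imp <- matrix(0, 40, 9)
  imp[20, 5] <- 1
  smi <- smooth_bmode(mk_img(imp, "envelope"), c(5.5, 7), wl)
  k_ax <- 21L
  k_lat <- 3L
  footprint <- smi$values[10:30, 4:6]
  expect_equal(footprint, matrix(1 / (k_ax * k_lat), k_ax, k_lat),
               tolerance = 1e-12)
  expect_equal(sum(smi$values > 1e-15), k_ax * k_lat)
  # a 1 x 1 kernel is the identity
  tiny <- smooth_bmode(mk_img(imp, "envelope"), c(0.1, 0.1), wl)
  expect_equal(tiny$values, imp)
  expect_error(smooth_bmode(mk_img(imp, "envelope"), c(5.5, 7), 1), "exceeds")
})

test_that("the normalization factor gates dim pixels and never dims bright ones", {
  B <- mk_img(matrix(c(10, 5, 10 * 10^(-61 / 20), 2e-9), 2, 2), "bmode")
  lam <- normalization_factor(B, gate_db = -60)
  expect_equal(lam$values[1, 1], 1)     # B = Bmax
  expect_equal(lam$values[2, 1], 2)     # B = Bmax / 2
  expect_equal(lam$values[1, 2], 1)     # -61 dB: gated
  expect_equal(lam$values[2, 2], 1)     # effectively zero: gated
  expect_true(all(lam$values >= 1))
  expect_error(normalization_factor(mk_img(matrix(0, 2, 2), "bmode")),
               "all-zero")
})

test_that("normalized intensity follows I * L * lambda^2", {
  I <- mk_img(matrix(2, 3, 3), "intensity")
  lam <- mk_img(matrix(3, 3, 3), "lambda")
  In <- normalize_intensity(I, lam, L = 8)
  expect_equal(In$values, matrix(144, 3, 3))
  # lambda = 1 (e.g. gated) -> L * I, so max-normalized dB is unchanged
  ones <- mk_img(matrix(1, 3, 3), "lambda")
  set.seed(8)
  Ir <- mk_img(matrix(stats::rexp(9), 3, 3), "intensity")
  expect_equal(log_compress(normalize_intensity(Ir, ones, 8))$values,
               log_compress(Ir)$values, tolerance = 1e-12)
  bad <- mk_img(matrix(1, 4, 3), "lambda")
  expect_error(normalize_intensity(I, bad, 8), "grid mismatch")
})

test_that("the overlay composites beam opacity over the grayscale B-mode", {
  bm <- mk_img(matrix(c(0, -30, -60, -60), 2, 2), "y")
  bm$kind <- "db"
  beam_vals <- matrix(c(0, -30, -90, -10), 2, 2)
  beam <- bm
  beam$values <- beam_vals
  rgb <- make_overlay(bm, beam, threshold = -20, dynamic_range = 60)
  # 0 dB beam pixel: fully opaque warm color (hot(1) = white)
  expect_equal(rgb[1, 1, ], c(1, 1, 1))
  # below threshold: pure grayscale
  gray <- (bm$values[2, 1] + 60) / 60
  expect_equal(rgb[2, 1, ], rep(gray, 3))
  # all-below-threshold beam leaves the B-mode untouched
  cold <- beam
  cold$values <- matrix(-50, 2, 2)
  rgb2 <- make_overlay(bm, cold, threshold = -20)
  expect_equal(rgb2[, , 1], (bm$values + 60) / 60)
  # threshold -Inf covers the full frame
  rgb3 <- make_overlay(bm, cold, threshold = -Inf)
  u <- (cold$values + 60) / 60
  red <- 3 * u
  red[red > 1] <- 1
  expect_equal(rgb3[, , 1], red)
  expect_error(make_overlay(bm, mk_img(matrix(1, 3, 2)), -20),
               "grid mismatch")
  raw <- mk_img(matrix(1, 2, 2), "y")
  expect_error(make_overlay(bm, raw, -20), "dB")
})

test_that("a global RF gain leaves the max-normalized reconstruction unchanged", {
  arr <- make_array(n_elements = 16, pitch = 0.3048e-3)
  cfg <- recon_config(fus_focus = c(0, 15e-3),
                      pw_angles = c(-6, 0, 6) * pi / 180)
  sp <- scene_spec(x_range = c(-1.5e-3, 1.5e-3), z_range = c(13e-3, 17e-3))
  sc <- build_scene(sp, seed = 6)
  acq <- simulate_acquisition(arr, sc, cfg, seed = 6)
  rec1 <- fus_pipeline(sc, arr, cfg, seed = 6, acquisition = acq,
                       z_range = c(12e-3, 18e-3))
  g <- 37.5
  acq2 <- acq
  acq2$visualization$data <- g * acq2$visualization$data
  acq2$bmode <- lapply(acq2$bmode, function(f) {
    f$data <- g * f$data
    f
  })
  rec2 <- fus_pipeline(sc, arr, cfg, seed = 6, acquisition = acq2,
                       z_range = c(12e-3, 18e-3))
  expect_equal(rec2$beam_db$values, rec1$beam_db$values, tolerance = 1e-9)
  expect_equal(rec2$bmode_db$values, rec1$bmode_db$values, tolerance = 1e-9)
  expect_equal(rec2$cf_map$values, rec1$cf_map$values, tolerance = 1e-9)
})

test_that("pipeline images have consistent kinds, grids and bounds", {
  arr <- make_array(n_elements = 16, pitch = 0.3048e-3)
  cfg <- recon_config(fus_focus = c(0, 15e-3),
                      pw_angles = c(-6, 0, 6) * pi / 180)
  sp <- scene_spec(x_range = c(-1.5e-3, 1.5e-3), z_range = c(13e-3, 17e-3))
  rec <- fus_pipeline(sp, arr, cfg, seed = 9, z_range = c(12e-3, 18e-3))
  expect_true(all(rec$cf_map$values >= 0 & rec$cf_map$values <= 1))
  expect_true(all(rec$intensity$values >= 0))
  expect_true(all(rec$intensity_norm$values >= 0))
  expect_true(all(rec$beam_db$values <= 0))
  expect_true(all(abs(rec$y_cf$values) <= abs(rec$y$values) + 1e-15))
  expect_true(same_grid <- identical(rec$beam_db$x_grid, rec$bmode_db$x_grid))
  expect_equal(dim(rec$overlay)[3], 3)
})
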