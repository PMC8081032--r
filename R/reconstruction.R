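#' Reconstruction configuration
#'
#' Collects the acquisition and reconstruction parameters of the beam
#' visualization pipeline: the FUS focal point, the steered plane-wave
#' angles used for B-mode formation, the receive f-number and apodization,
#' the echogenicity gate, smoothing/median kernel sizes (in wavelengths),
#' display dynamic ranges and the overlay threshold.
#'
#' @param fus_focus FUS focal point `c(x, z)` in meters (default 30 mm on
#'   axis).
#' @param pw_angles Plane-wave steering angles in radians (default seven
#'   angles from -18 to +18 degrees in 6-degree steps).
#' @param rx_f_number Receive f-number (default 1).
#' @param apodization Receive apodization, `"hann"` (default) or `"none"`.
#' @param n_cycles_vis Cycles in the focused visualization pulse (default 2).
#' @param n_cycles_therapy Cycles in the mock therapy burst (default 25;
#'   logged but never reconstructed).
#' @param gate_db Echogenicity gate: pixels whose smoothed B-mode falls below
#'   this level (dB re max) keep a normalization factor of 1 (default -60).
#'   Use `-Inf` to disable the gate.
#' @param smooth_kernel_wl B-mode moving-average kernel `c(axial, lateral)`
#'   in wavelengths (default 5.5 x 7).
#' @param median_kernel_wl Median-filter kernel `c(axial, lateral)` in
#'   wavelengths used by the MSE protocol (default 5.5 x 5).
#' @param display_dr Display dynamic range in dB (default 60).
#' @param overlay_threshold Beam-overlay opacity threshold in dB (default
#'   -20).
#' @return Object of class `fus_config`.
#' @export
recon_config <- function(fus_focus = c(0, 30e-3),
                         pw_angles = seq(-18, 18, by = 6) * pi / 180,
                         rx_f_number = 1, apodization = c("hann", "none"),
                         n_cycles_vis = 2, n_cycles_therapy = 25,
                         gate_db = -60, smooth_kernel_wl = c(5.5, 7),
                         median_kernel_wl = c(5.5, 5), display_dr = 60,
                         overlay_threshold = -20) {
  apodization <- match.arg(apodization)
  if (rx_f_number <= 0) stop("rx_f_number must be > 0", call. = FALSE)
  if (gate_db >= 0) stop("gate_db must be < 0", call. = FALSE)
  if (any(smooth_kernel_wl <= 0) || any(median_kernel_wl <= 0))
    stop("kernel sizes must be > 0", call. = FALSE)
  if (any(abs(pw_angles) >= pi / 2))
    stop("plane-wave angles must be within +/-90 degrees", call. = FALSE)
  structure(
    list(fus_focus = fus_focus, pw_angles = pw_angles,
         rx_f_number = rx_f_number, apodization = apodization,
         n_cycles_vis = n_cycles_vis, n_cycles_therapy = n_cycles_therapy,
         gate_db = gate_db, smooth_kernel_wl = smooth_kernel_wl,
         median_kernel_wl = median_kernel_wl, display_dr = display_dr,
         overlay_threshold = overlay_threshold),
    class = "fus_config")
}

# nearest odd integer >= 1
odd_px <- function(x) max(1L, 2L * as.integer(round((x - 1) / 2)) + 1L)

kernel_px <- function(kernel_wl, wavelength, dz, dx) {
  c(odd_px(kernel_wl[1] * wavelength / dz),
    odd_px(kernel_wl[2] * wavelength / dx))
}

#' Pulse intensity field from CF-weighted beamformed data
#'
#' Sliding axial integral of the squared beamformed data over the pulse
#' length: `I(x, z) = sum_{i=0}^{L-1} dz * |y_CF(x, z + i)|^2`, approximating
#' a pulse intensity integral per image point. The window is truncated
#' (zero-padded) at the deep edge.
#'
#' @param y_cf RF-beamformed `fus_image` (kind `"y_cf"` or `"y"`).
#' @param L Visualization pulse length in samples (>= 1).
#' @param dz Axial sampling period in meters (default: the z-grid step).
#' @return Nonnegative `fus_image` of kind `"intensity"`.
#' @export
intensity_field <- function(y_cf, L, dz = NULL) {
  stopifnot(inherits(y_cf, "fus_image"))
  if (!y_cf$kind %in% c("y", "y_cf"))
    stop("intensity_field requires RF-domain beamformed data", call. = FALSE)
  nz <- nrow(y_cf$values)
  L <- as.integer(L)
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  if (L > nz) stop("pulse length L exceeds the axial extent", call. = FALSE)
  if (is.null(dz)) dz <- if (nz > 1) y_cf$z_grid[2] - y_cf$z_grid[1] else 1
  v2 <- y_cf$values^2
  cs <- rbind(0, apply(v2, 2, cumsum))
  hi <- pmin(seq_len(nz) + L - 1L, nz)
  I <- dz * (cs[hi + 1L, , drop = FALSE] - cs[seq_len(nz), , drop = FALSE])
  I[I < 0] <- 0 # fp guard
  beamformed_image(I, y_cf$x_grid, y_cf$z_grid, "intensity")
}

#' Smooth a B-mode envelope with a moving-average kernel
#'
#' Convolves the linear (pre-log) envelope with an axial x lateral moving
#' average whose size is given in wavelengths and converted to pixels
#' (rounded to the nearest odd integer >= 1). Edges are handled by symmetric
#' reflection. This removes speckle so that only large-scale echogenicity
#' drives the normalization.
#'
#' @param env Linear envelope `fus_image` (kind `"envelope"` or `"bmode"`).
#' @param kernel_wl Kernel size `c(axial, lateral)` in wavelengths
#'   (default 5.5 x 7).
#' @param wavelength Acoustic wavelength in meters (c / f0).
#' @return Nonnegative `fus_image` of kind `"bmode"`.
#' @export
smooth_bmode <- function(env, kernel_wl = c(5.5, 7), wavelength) {
  stopifnot(inherits(env, "fus_image"))
  if (!env$kind %in% c("envelope", "bmode"))
    stop("smooth_bmode requires a linear envelope image", call. = FALSE)
  dz <- env$z_grid[2] - env$z_grid[1]
  dx <- env$x_grid[2] - env$x_grid[1]
  k <- kernel_px(kernel_wl, wavelength, dz, dx)
  if (k[1] > nrow(env$values) || k[2] > ncol(env$values))
    stop("smoothing kernel exceeds the image", call. = FALSE)
  sm <- movavg_reflect_cpp(env$values, k[1], k[2])
  sm[sm < 0] <- 0
  beamformed_image(sm, env$x_grid, env$z_grid, "bmode")
}

#' Echogenicity normalization factor
#'
#' `lambda(x, z) = B_max / B(x, z)` from the smoothed B-mode envelope,
#' except at gated points — where `B` is below `gate_db` relative to its
#' maximum, assumed noise rather than backscatter — which keep `lambda = 1`.
#' On un-gated points `lambda >= 1`.
#'
#' @param B Smoothed B-mode `fus_image` (kind `"bmode"` or `"envelope"`),
#'   nonnegative with a positive maximum.
#' @param gate_db Gate level in dB re max (default -60); `-Inf` disables the
#'   gate (pixels with `B = 0` still keep `lambda = 1`).
#' @return `fus_image` of kind `"lambda"`.
#' @export
normalization_factor <- function(B, gate_db = -60) {
  stopifnot(inherits(B, "fus_image"))
  Bmax <- max(B$values)
  if (Bmax <= 0) stop("all-zero B-mode image", call. = FALSE)
  lam <- matrix(1, nrow(B$values), ncol(B$values))
  keep <- B$values > 0 & 20 * log10(pmax(B$values, .Machine$double.xmin) /
                                      Bmax) >= gate_db
  lam[keep] <- Bmax / B$values[keep]
  beamformed_image(lam, B$x_grid, B$z_grid, "lambda")
}

#' Normalize the intensity field by echogenicity
#'
#' `I_norm(x, z) = I(x, z) * L * lambda(x, z)^2`: the factor `L` accounts
#' for the L samples of the pulse intensity integral and `lambda` is squared
#' because the beamformed data are squared to form the intensity. `L` is a
#' global constant and cancels under max-normalization.
#'
#' @param I Intensity `fus_image`.
#' @param lam Normalization-factor `fus_image` on the same grid.
#' @param L Visualization pulse length in samples.
#' @return `fus_image` of kind `"intensity_norm"`.
#' @export
normalize_intensity <- function(I, lam, L) {
  stopifnot(inherits(I, "fus_image"), inherits(lam, "fus_image"))
  if (!same_grid(I, lam)) stop("grid mismatch", call. = FALSE)
  beamformed_image(I$values * L * lam$values^2, I$x_grid, I$z_grid,
                   "intensity_norm")
}

hot_colormap <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  list(r = pmin(1, 3 * u),
       g = pmin(1, pmax(0, 3 * u - 1)),
       b = pmin(1, pmax(0, 3 * u - 2)))
}

#' Compose the beam-over-B-mode overlay
#'
#' Renders the max-normalized dB B-mode in grayscale and overlays the
#' max-normalized dB beam reconstruction in a warm colormap whose opacity
#' ramps linearly from 0 at `threshold` to 1 at 0 dB; beam pixels below the
#' threshold are fully transparent.
#'
#' @param bmode_db,beam_db Max-normalized dB `fus_image`s on a common grid.
#' @param threshold Overlay opacity threshold in dB (default -20); `-Inf`
#'   makes the beam layer cover the whole frame at full opacity.
#' @param dynamic_range Grayscale display dynamic range in dB (default 60).
#' @param path Optional PNG output path.
#' @return Invisibly, an `n_z x n_x x 3` RGB array in \[0, 1\].
#' @export
make_overlay <- function(bmode_db, beam_db, threshold = -20,
                         dynamic_range = 60, path = NULL) {
  stopifnot(inherits(bmode_db, "fus_image"), inherits(beam_db, "fus_image"))
  if (!same_grid(bmode_db, beam_db)) stop("grid mismatch", call. = FALSE)
  if (!identical(bmode_db$kind, "db") || !identical(beam_db$kind, "db"))
    stop("both inputs must be max-normalized dB images", call. = FALSE)
  gray <- pmin(pmax((bmode_db$values + dynamic_range) / dynamic_range, 0), 1)
  if (is.infinite(threshold) && threshold < 0) {
    alpha <- matrix(1, nrow(gray), ncol(gray))
    u <- pmin(pmax((beam_db$values + dynamic_range) / dynamic_range, 0), 1)
  } else {
    u <- (beam_db$values - threshold) / (-threshold)
    u <- pmin(pmax(u, 0), 1)
    alpha <- u
  }
  cm <- hot_colormap(u)
  rgb <- array(0, dim = c(nrow(gray), ncol(gray), 3))
  rgb[, , 1] <- (1 - alpha) * gray + alpha * cm$r
  rgb[, , 2] <- (1 - alpha) * gray + alpha * cm$g
  rgb[, , 3] <- (1 - alpha) * gray + alpha * cm$b
  if (!is.null(path)) png::writePNG(rgb, target = path)
  invisible(rgb)
}
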