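#' End-to-end beam-visualization pipeline
#'
#' Runs the full chain on one scene: simulate the acquisition (one focused
#' visualization transmit plus steered plane waves), beamform the focused
#' frame by DAS with optional coherence-factor weighting, integrate the
#' pulse intensity field, form the compounded B-mode, normalize the
#' intensity field by echogenicity, log-compress, and compose the overlay.
#'
#' @param scene A `fus_scene` (or a `fus_scene_spec`, realized with `seed`).
#' @param array A `fus_array`.
#' @param config A `fus_config`.
#' @param seed Integer seed for scene realization / sensor noise.
#' @param beamformer `"das-cf"` (default) weights the beamformed data by the
#'   coherence factor; `"das"` is plain delay-and-sum.
#' @param normalize Apply echogenicity normalization (default TRUE).
#' @param gate_db Echogenicity gate passed to [normalization_factor()]
#'   (default from `config`; `-Inf` disables the gate).
#' @param z_range Depth window `c(z_min, z_max)` of the image grid; default
#'   spans the scene (or the focus) with a small margin.
#' @param opts A `fus_sim_options`.
#' @param acquisition Optionally, a precomputed `fus_acquisition` (skips the
#'   simulation; `scene` is then ignored).
#' @param keep_rf Keep the RF frames in the returned object (default FALSE).
#' @return Object of class `fus_recon` with the intermediate and final
#'   images: `y`, `cf_map`, `y_cf`, `intensity`, `bmode_env`, `bmode_smooth`,
#'   `bmode_db`, `lambda`, `intensity_norm`, `beam_db`, `overlay`, plus
#'   `pulse`, `config`, `seed`.
#' @export
fus_pipeline <- function(scene, array = make_array(), config = recon_config(),
                         seed = 1L, beamformer = c("das-cf", "das"),
                         normalize = TRUE, gate_db = config$gate_db,
                         z_range = NULL, opts = sim_options(),
                         acquisition = NULL, keep_rf = FALSE) {
  beamformer <- match.arg(beamformer)
  if (inherits(scene, "fus_scene_spec")) scene <- build_scene(scene, seed)
  if (is.null(acquisition)) {
    acq <- simulate_acquisition(array, scene, config, seed = seed,
                                opts = opts)
  } else acq <- acquisition
  if (is.null(z_range)) {
    z_range <- if (length(scene$z))
      c(max(1e-3, min(scene$z) - 2e-3), max(scene$z) + 2e-3)
    else config$fus_focus[2] + c(-8e-3, 8e-3)
  }
  pulse <- acq$visualization$pulse

  bf <- das_focused(acq$visualization, array, z_range = z_range,
                    f_number = config$rx_f_number,
                    apodization = config$apodization)
  y_cf <- if (beamformer == "das-cf") apply_cf(bf$y, bf$cf_map) else bf$y
  dz <- bf$y$z_grid[2] - bf$y$z_grid[1]
  I <- intensity_field(y_cf, pulse$L, dz)

  pw <- lapply(acq$bmode, function(rf)
    das_plane_wave(rf, array, z_grid = bf$y$z_grid,
                   f_number = config$rx_f_number,
                   apodization = config$apodization)$y)
  bmode_env <- envelope(compound(pw))
  wl <- array_wavelength(array)
  bmode_smooth <- smooth_bmode(bmode_env, config$smooth_kernel_wl, wl)
  bmode_db <- log_compress(bmode_env, -config$display_dr)

  lam <- normalization_factor(bmode_smooth, gate_db)
  I_final <- if (normalize) normalize_intensity(I, lam, pulse$L) else I
  beam_db <- log_compress(I_final, -config$display_dr)
  overlay <- make_overlay(bmode_db, beam_db, config$overlay_threshold,
                          config$display_dr)

  structure(
    list(y = bf$y, cf_map = bf$cf_map, y_cf = y_cf, intensity = I,
         bmode_env = bmode_env, bmode_smooth = bmode_smooth,
         bmode_db = bmode_db, lambda = lam, intensity_norm = I_final,
         beam_db = beam_db, overlay = overlay, pulse = pulse,
         config = config, scene = scene, seed = seed, normalize = normalize,
         beamformer = beamformer,
         acquisition = if (keep_rf) acq else NULL),
    class = "fus_recon")
}

#' @export
print.fus_recon <- function(x, ...) {
  pk <- arg_max_image(x$intensity_norm)
  cat(sprintf(
    "<fus_recon> %s%s, %d x %d grid\n  intensity peak at x = %.2f mm, z = %.2f mm\n",
    x$beamformer, if (x$normalize) " + echogenicity normalization" else "",
    nrow(x$beam_db$values), ncol(x$beam_db$values),
    pk["x"] * 1e3, pk["z"] * 1e3))
  invisible(x)
}

#' Grid location of an image's maximum
#'
#' @param img A `fus_image`.
#' @return Named vector `c(x, z)` of the maximum pixel's coordinates (m).
#' @export
arg_max_image <- function(img) {
  stopifnot(inherits(img, "fus_image"))
  ij <- arrayInd(which.max(img$values), dim(img$values))
  c(x = img$x_grid[ij[2]], z = img$z_grid[ij[1]])
}

#' Lateral profile of an image at a given depth
#'
#' @param img A `fus_image`.
#' @param z Depth in meters (nearest grid row is used).
#' @return List with `x` (lateral coordinates) and `values`.
#' @export
lateral_profile <- function(img, z) {
  stopifnot(inherits(img, "fus_image"))
  iz <- which.min(abs(img$z_grid - z))
  list(x = img$x_grid, values = img$values[iz, ])
}

#' Axial profile of an image at a given lateral position
#'
#' @param img A `fus_image`.
#' @param x Lateral position in meters (nearest grid line is used).
#' @return List with `z` (depth coordinates) and `values`.
#' @export
axial_profile <- function(img, x) {
  stopifnot(inherits(img, "fus_image"))
  ix <- which.min(abs(img$x_grid - x))
  list(z = img$z_grid, values = img$values[, ix])
}

#' Crop a beamformed image to a region of interest
#'
#' @param img A `fus_image`.
#' @param x_range,z_range Ranges in meters; grid points outside are dropped.
#' @return The cropped `fus_image`.
#' @export
crop_image <- function(img, x_range = NULL, z_range = NULL) {
  stopifnot(inherits(img, "fus_image"))
  ix <- if (is.null(x_range)) seq_along(img$x_grid)
        else which(img$x_grid >= x_range[1] & img$x_grid <= x_range[2])
  iz <- if (is.null(z_range)) seq_along(img$z_grid)
        else which(img$z_grid >= z_range[1] & img$z_grid <= z_range[2])
  if (!length(ix) || !length(iz)) stop("empty crop region", call. = FALSE)
  beamformed_image(img$values[iz, ix, drop = FALSE], img$x_grid[ix],
                   img$z_grid[iz], img$kind)
}
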