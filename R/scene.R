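#' Describe a synthetic scatterer scene
#'
#' A scene is a rectangular field of sub-resolution scatterers (fully
#' developed speckle when the density is high enough), optionally modulated
#' by echogenicity regions (e.g. hyper-/hypoechoic disks) and augmented with
#' strong isolated point targets (wires). Amplitudes of background
#' scatterers are drawn from a zero-mean normal distribution; a region with
#' echogenicity offset `g` dB multiplies the amplitude scale of scatterers
#' inside it by `10^(g/20)`.
#'
#' The background scatterer count is `density_per_cell` per -6 dB resolution
#' cell, where the cell is approximated as (1.028 * lambda * f_number)
#' laterally by (n_cycles * lambda / 2) axially for the imaging pulse.
#'
#' @param x_range,z_range Field extent in meters (`z_range` > 0). Omit both
#'   (NULL) for a scene with no speckle background (e.g. a wire in water).
#' @param density_per_cell Background scatterers per resolution cell
#'   (default 15, enough for fully developed speckle).
#' @param sigma Background amplitude standard deviation (linear units).
#' @param c Sound speed of the medium (m/s); 1540 for phantom/tissue scenes,
#'   1480 for water scenes.
#' @param f0 Imaging center frequency (Hz) used for the resolution cell.
#' @param f_number,n_cycles Receive f-number and pulse cycles used for the
#'   resolution-cell approximation.
#' @param regions List of echogenicity regions, see [region_disk()].
#' @param points List of isolated strong targets, see [point_target()].
#' @return Object of class `fus_scene_spec`.
#' @export
scene_spec <- function(x_range = NULL, z_range = NULL, density_per_cell = 15,
                       sigma = 1, c = 1540, f0 = 5e6, f_number = 1,
                       n_cycles = 2, regions = list(), points = list()) {
  has_bg <- !is.null(x_range) && !is.null(z_range)
  if (has_bg) {
    stopifnot(length(x_range) == 2L, length(z_range) == 2L)
    if (any(z_range <= 0)) stop("invalid spec: z_range must be > 0",
                                call. = FALSE)
    if (density_per_cell <= 0)
      stop("invalid spec: density_per_cell must be > 0 for a background",
           call. = FALSE)
  }
  structure(
    list(x_range = x_range, z_range = z_range,
         density_per_cell = density_per_cell, sigma = sigma, c = c, f0 = f0,
         f_number = f_number, n_cycles = n_cycles, regions = regions,
         points = points, has_background = has_bg),
    class = "fus_scene_spec")
}

#' Circular echogenicity region
#'
#' @param center Disk center `c(x, z)` in meters.
#' @param radius Disk radius in meters.
#' @param offset_db Echogenicity offset in dB relative to the background
#'   (e.g. +15 for a hyperechoic, -15 for a hypoechoic contrast target).
#' @param label Region tag attached to scatterers inside the disk.
#' @export
region_disk <- function(center, radius, offset_db, label = "disk") {
  stopifnot(length(center) == 2L, radius > 0)
  list(type = "disk", center = center, radius = radius,
       offset_db = offset_db, label = label)
}

#' Isolated strong point target
#'
#' A single scatterer whose amplitude is `boost_db` above the background
#' amplitude scale (default 40 dB), emulating a wire or pin target.
#'
#' @param x,z Position in meters (z > 0).
#' @param boost_db Amplitude boost in dB over the background scale `sigma`.
#' @param label Tag for the scatterer.
#' @export
point_target <- function(x, z, boost_db = 40, label = "point") {
  if (z <= 0) stop("invalid spec: point target z must be > 0", call. = FALSE)
  list(x = x, z = z, boost_db = boost_db, label = label)
}

res_cell_area <- function(spec) {
  lam <- spec$c / spec$f0
  (1.028 * lam * spec$f_number) * (spec$n_cycles * lam / 2)
}

#' Realize a scatterer field from a scene description
#'
#' Draws background scatterer positions uniformly over the field and
#' amplitudes from N(0, sigma^2), applies region echogenicity offsets, and
#' appends point targets. Regeneration with the same spec and seed is
#' bit-identical; the caller's RNG state is left untouched.
#'
#' @param spec A `fus_scene_spec`.
#' @param seed Integer RNG seed.
#' @return Object of class `fus_scene` with vectors `x`, `z`, `amplitude`,
#'   `label`, plus `c`, `seed`, and the originating `spec`.
#' @examples
#' sp <- scene_spec(x_range = c(-2e-3, 2e-3), z_range = c(28e-3, 32e-3))
#' sc <- build_scene(sp, seed = 1)
#' length(sc$x)
#' @export
build_scene <- function(spec, seed) {
  stopifnot(inherits(spec, "fus_scene_spec"))
  seed <- as.integer(seed)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  x <- z <- amp <- numeric(0)
  label <- character(0)
  if (spec$has_background) {
    area <- diff(spec$x_range) * diff(spec$z_range)
    n <- max(1L, as.integer(round(spec$density_per_cell * area /
                                    res_cell_area(spec))))
    x <- stats::runif(n, spec$x_range[1], spec$x_range[2])
    z <- stats::runif(n, spec$z_range[1], spec$z_range[2])
    amp <- stats::rnorm(n, 0, spec$sigma)
    label <- rep("background", n)
    for (rg in spec$regions) {
      if (!identical(rg$type, "disk"))
        stop("invalid spec: unknown region type ", rg$type, call. = FALSE)
      inside <- (x - rg$center[1])^2 + (z - rg$center[2])^2 <= rg$radius^2
      amp[inside] <- amp[inside] * 10^(rg$offset_db / 20)
      label[inside] <- rg$label
    }
  }
  for (pt in spec$points) {
    x <- c(x, pt$x)
    z <- c(z, pt$z)
    amp <- c(amp, spec$sigma * 10^(pt$boost_db / 20))
    label <- c(label, pt$label)
  }
  if (any(!is.finite(amp)))
    stop("invalid spec: non-finite scatterer amplitude", call. = FALSE)
  structure(
    list(x = x, z = z, amplitude = amp, label = label, c = spec$c,
         seed = seed, spec = spec),
    class = "fus_scene")
}

#' @export
print.fus_scene <- function(x, ...) {
  cat(sprintf("<fus_scene> %d scatterers (seed %d, c = %g m/s)\n",
              length(x$x), x$seed, x$c))
  if (length(x$x)) {
    tab <- table(x$label)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
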