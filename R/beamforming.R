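#' Construct a beamformed image
#'
#' A gridded image on a lateral-by-depth grid with a `kind` tag recording
#' what the values are: RF-beamformed data (`"y"`, `"y_cf"`), a coherence
#' factor map (`"cf_map"`, values in \[0, 1\]), a nonnegative envelope or
#' smoothed B-mode (`"envelope"`, `"bmode"`), an intensity field
#' (`"intensity"`, `"intensity_norm"`), a normalization-factor map
#' (`"lambda"`), or a max-normalized dB image (`"db"`, values <= 0).
#'
#' @param values Numeric matrix `n_z x n_x` (rows are depths).
#' @param x_grid,z_grid Strictly increasing lateral / depth coordinates (m).
#' @param kind One of `"y"`, `"y_cf"`, `"cf_map"`, `"envelope"`, `"bmode"`,
#'   `"intensity"`, `"intensity_norm"`, `"lambda"`, `"db"`.
#' @return Object of class `fus_image`.
#' @export
beamformed_image <- function(values, x_grid, z_grid,
                             kind = c("y", "y_cf", "cf_map", "envelope",
                                      "bmode", "intensity", "intensity_norm",
                                      "lambda", "db")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != length(z_grid) || ncol(values) != length(x_grid))
    stop("values must be n_z x n_x", call. = FALSE)
  if (length(z_grid) > 1 && any(diff(z_grid) <= 0))
    stop("z_grid must be strictly increasing", call. = FALSE)
  if (length(x_grid) > 1 && any(diff(x_grid) <= 0))
    stop("x_grid must be strictly increasing", call. = FALSE)
  if (kind == "cf_map" && (min(values) < 0 || max(values) > 1))
    stop("cf_map values must lie in [0, 1]", call. = FALSE)
  if (kind %in% c("envelope", "bmode", "intensity", "intensity_norm") &&
      min(values) < 0)
    stop(kind, " values must be nonnegative", call. = FALSE)
  structure(list(values = values, x_grid = as.numeric(x_grid),
                 z_grid = as.numeric(z_grid), kind = kind),
            class = "fus_image")
}

#' @export
print.fus_image <- function(x, ...) {
  cat(sprintf("<fus_image> kind '%s', %d x %d (z x x), x in [%.2f, %.2f] mm, z in [%.2f, %.2f] mm\n",
              x$kind, nrow(x$values), ncol(x$values),
              min(x$x_grid) * 1e3, max(x$x_grid) * 1e3,
              min(x$z_grid) * 1e3, max(x$z_grid) * 1e3))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-12) {
  length(a$x_grid) == length(b$x_grid) &&
    length(a$z_grid) == length(b$z_grid) &&
    max(abs(a$x_grid - b$x_grid)) <= tol &&
    max(abs(a$z_grid - b$z_grid)) <= tol
}

default_z_grid <- function(rf, z_range = NULL) {
  dz <- rf$array$c / (2 * rf$fs)
  if (is.null(z_range)) {
    z_max <- (rf$t0 + (nrow(rf$data) - 1) / rf$fs) * rf$array$c / 2
    seq(dz, z_max, by = dz)
  } else {
    seq(max(dz, z_range[1]), z_range[2], by = dz)
  }
}

das_run <- function(rf, array, tau_tx, x_grid, z_grid, f_number, apodization,
                    cf_samples, return_samples) {
  if (f_number <= 0) stop("f_number must be > 0", call. = FALSE)
  res <- das_core_cpp(rf$data, rf$fs, rf$t0, array$element_x, x_grid, z_grid,
                      tau_tx, array$c, f_number,
                      as.integer(apodization == "hann"),
                      as.integer(cf_samples == "apodized"),
                      as.integer(return_samples))
  if (res$n_oob > 0)
    warning("image grid extends outside the record window; ",
            "out-of-window samples treated as zero", call. = FALSE)
  res
}

#' Delay-and-sum beamforming of a focused transmit
#'
#' Dynamic receive focusing with a dynamic receive subaperture of fixed
#' f-number centered on each image line. The subaperture half-width at depth
#' `z` is `z / (2 * f_number)`, clipped to the array; delayed channel samples
#' are gathered with linear interpolation, Hanning-apodized over the nominal
#' subaperture width, and summed. The per-point coherence factor is computed
#' from the same delayed samples (apodized by default, switchable).
#'
#' The delay law for a point (x_c, z) and element at x is
#' `tau_F(x_c) + (z + sqrt(z^2 + (x - x_c)^2)) / c`, where `tau_F(x_c)` is
#' the transmit focusing delay of the element at the line position.
#'
#' @param rf A `fus_rf` from a focused transmit.
#' @param array A `fus_array` (defaults to the one stored in `rf`).
#' @param z_grid Depth grid (m); default spacing `c / (2 fs)` over the
#'   record window, or restricted to `z_range`.
#' @param z_range Optional `c(z_min, z_max)` shortcut for `z_grid`.
#' @param f_number Receive f-number (> 0), default 1.
#' @param apodization `"hann"` (default) or `"none"`.
#' @param cf_samples Compute the coherence factor from `"apodized"`
#'   (default) or `"raw"` delayed samples.
#' @param return_samples If TRUE also return the un-summed delayed
#'   subaperture samples as an `n_z x n_x x n_elements` array (NA outside
#'   the subaperture). Intended for small problems.
#' @return List with `y` (RF-beamformed `fus_image`), `cf_map` (`fus_image`),
#'   `n_used` (elements per point), and optionally `samples`.
#' @export
das_focused <- function(rf, array = rf$array, z_grid = NULL, z_range = NULL,
                        f_number = 1, apodization = c("hann", "none"),
                        cf_samples = c("apodized", "raw"),
                        return_samples = FALSE) {
  stopifnot(inherits(rf, "fus_rf"))
  apodization <- match.arg(apodization)
  cf_samples <- match.arg(cf_samples)
  if (!identical(rf$tx$kind, "focused"))
    stop("rf must come from a focused transmit", call. = FALSE)
  if (is.null(z_grid)) z_grid <- default_z_grid(rf, z_range)
  x_grid <- array$element_x # one image line per element
  tauF <- rf$tx$delays
  tau_tx <- outer(z_grid / array$c, tauF, "+")
  res <- das_run(rf, array, tau_tx, x_grid, z_grid, f_number, apodization,
                 cf_samples, return_samples)
  out <- list(
    y = beamformed_image(res$y, x_grid, z_grid, "y"),
    cf_map = beamformed_image(res$cf, x_grid, z_grid, "cf_map"),
    n_used = res$n_used)
  if (return_samples) out$samples <- res$samples
  out
}

#' Delay-and-sum beamforming of a steered plane-wave transmit
#'
#' Standard plane-wave DAS: the transmit time to a point (x, z) is
#' `(x sin(theta) + z cos(theta)) / c` plus the event's delay-normalization
#' offset; the receive path and dynamic aperture are as in [das_focused()].
#'
#' @inheritParams das_focused
#' @param rf A `fus_rf` from a plane-wave transmit.
#' @return List with `y` and `cf_map` as in [das_focused()].
#' @export
das_plane_wave <- function(rf, array = rf$array, z_grid = NULL,
                           z_range = NULL, f_number = 1,
                           apodization = c("hann", "none"),
                           cf_samples = c("apodized", "raw")) {
  stopifnot(inherits(rf, "fus_rf"))
  apodization <- match.arg(apodization)
  cf_samples <- match.arg(cf_samples)
  if (!identical(rf$tx$kind, "plane_wave"))
    stop("rf must come from a plane-wave transmit", call. = FALSE)
  if (is.null(z_grid)) z_grid <- default_z_grid(rf, z_range)
  x_grid <- array$element_x
  th <- rf$tx$angle
  tau_tx <- (outer(z_grid * cos(th), x_grid * sin(th), "+")) / array$c +
    rf$tx$t_ref
  res <- das_run(rf, array, tau_tx, x_grid, z_grid, f_number, apodization,
                 cf_samples, FALSE)
  list(y = beamformed_image(res$y, x_grid, z_grid, "y"),
       cf_map = beamformed_image(res$cf, x_grid, z_grid, "cf_map"))
}

#' Coherence factor of a receive subaperture
#'
#' The ratio of coherent to incoherent energy across `N` delayed channel
#' samples: `CF = |sum(s)|^2 / (N * sum(s^2))`, defined as 0 when the
#' denominator vanishes. Bounded in \[0, 1\] by Cauchy-Schwarz and invariant
#' to a common scaling of the samples.
#'
#' @param s Numeric vector of delayed channel samples (NAs are dropped,
#'   matching elements outside the subaperture).
#' @return CF in \[0, 1\].
#' @examples
#' coherence_factor(c(1, 1, 0, 0)) # 0.5
#' @export
coherence_factor <- function(s) {
  s <- s[!is.na(s)]
  n <- length(s)
  if (n < 1) stop("need at least one sample", call. = FALSE)
  denom <- n * sum(s^2)
  if (denom == 0) return(0)
  min(1, sum(s)^2 / denom)
}

#' Apply a coherence-factor map to beamformed data
#'
#' Pointwise product `y_CF = CF * y`; since CF is in \[0, 1\], the output
#' magnitude never exceeds the input anywhere.
#'
#' @param y RF-beamformed `fus_image` (kind `"y"`).
#' @param cf_map Coherence-factor `fus_image` (kind `"cf_map"`) on the same
#'   grid.
#' @return `fus_image` of kind `"y_cf"`.
#' @export
apply_cf <- function(y, cf_map) {
  stopifnot(inherits(y, "fus_image"), inherits(cf_map, "fus_image"))
  if (!same_grid(y, cf_map)) stop("grid mismatch", call. = FALSE)
  beamformed_image(y$values * cf_map$values, y$x_grid, y$z_grid, "y_cf")
}

#' Coherent compounding of RF-beamformed images
#'
#' Pointwise sum of RF-domain (pre-envelope) beamformed images on a common
#' grid, e.g. the steered plane-wave images forming a compounded B-mode.
#'
#' @param images List of `fus_image` objects of kind `"y"` or `"y_cf"`.
#' @return `fus_image` of kind `"y"`.
#' @export
compound <- function(images) {
  stopifnot(length(images) >= 1)
  ref <- images[[1]]
  for (im in images) {
    stopifnot(inherits(im, "fus_image"))
    if (!im$kind %in% c("y", "y_cf"))
      stop("compounding requires RF-domain (pre-envelope) images",
           call. = FALSE)
    if (!same_grid(im, ref)) stop("grid mismatch", call. = FALSE)
  }
  v <- Reduce(`+`, lapply(images, function(im) im$values))
  beamformed_image(v, ref$x_grid, ref$z_grid, "y")
}

#' Envelope detection
#'
#' Magnitude of the analytic signal computed per image line along depth
#' (negative-frequency components removed via the FFT).
#'
#' @param y RF-domain `fus_image` (kind `"y"` or `"y_cf"`).
#' @return Nonnegative `fus_image` of kind `"envelope"`.
#' @export
envelope <- function(y) {
  stopifnot(inherits(y, "fus_image"))
  if (!y$kind %in% c("y", "y_cf"))
    stop("envelope detection requires RF-domain values", call. = FALSE)
  v <- y$values
  n <- nrow(v)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  env <- abs(stats::mvfft(stats::mvfft(v) * h, inverse = TRUE) / n)
  beamformed_image(env, y$x_grid, y$z_grid, "envelope")
}

#' Logarithmic compression
#'
#' Max-normalized dB image: `20 log10(v / max)` for envelope-type images and
#' `10 log10(v / max)` for intensity-type images, clipped below at
#' `floor_db`. The maximum pixel maps to 0 dB.
#'
#' @param img Nonnegative `fus_image` (kind `"envelope"`, `"bmode"`,
#'   `"intensity"` or `"intensity_norm"`) with a positive maximum.
#' @param floor_db Lower clip in dB (default -60).
#' @return `fus_image` of kind `"db"`.
#' @export
log_compress <- function(img, floor_db = -60) {
  stopifnot(inherits(img, "fus_image"))
  fac <- switch(img$kind,
                envelope = 20, bmode = 20,
                intensity = 10, intensity_norm = 10,
                stop("log compression requires an envelope or intensity image",
                     call. = FALSE))
  m <- max(img$values)
  if (m <= 0) stop("all-zero image cannot be log-compressed", call. = FALSE)
  db <- fac * log10(pmax(img$values / m, 10^(floor_db / fac)))
  beamformed_image(db, img$x_grid, img$z_grid, "db")
}
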