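#' Theoretical -3 dB beamwidth of a focused source
#'
#' Continuous-wave approximation `R = 1.028 * lambda * f_number`.
#'
#' @param wavelength Excitation wavelength (any length unit; the result is
#'   in the same unit).
#' @param f_number F-number of the source (focal depth / aperture).
#' @return Lateral -3 dB beamwidth.
#' @examples
#' theoretical_beamwidth(0.296, 0.756) # ~0.23 (mm in, mm out)
#' @export
theoretical_beamwidth <- function(wavelength, f_number) {
  if (wavelength <= 0 || f_number <= 0)
    stop("wavelength and f_number must be > 0", call. = FALSE)
  1.028 * wavelength * f_number
}

#' Theoretical -3 dB depth of field of a focused source
#'
#' Continuous-wave approximation `DOF = 7.08 * lambda * f_number^2`.
#'
#' @inheritParams theoretical_beamwidth
#' @return Axial -3 dB depth of field.
#' @examples
#' theoretical_dof(0.296, 0.756) # ~1.20
#' @export
theoretical_dof <- function(wavelength, f_number) {
  if (wavelength <= 0 || f_number <= 0)
    stop("wavelength and f_number must be > 0", call. = FALSE)
  7.08 * wavelength * f_number^2
}

#' Width of a profile at a dB level below its peak
#'
#' Finds the two crossings of `peak + level_db` nearest the global maximum
#' of a 1-D dB profile, locating each by linear interpolation in dB, and
#' returns the distance between them. Used for measured beamwidths (lateral
#' profile) and depths of field (axial profile).
#'
#' @param profile Numeric vector of dB samples with a unique global maximum.
#' @param coords Coordinates of the samples (same length, increasing).
#' @param level_db Level below the peak, e.g. -3 or -6.
#' @return Width in the units of `coords`.
#' @export
measure_width <- function(profile, coords, level_db = -3) {
  stopifnot(length(profile) == length(coords), level_db < 0)
  p <- which.max(profile)
  thr <- profile[p] + level_db
  cross <- function(idx) {
    # first crossing of thr walking away from the peak along idx
    for (i in seq_along(idx)[-1]) {
      a <- idx[i - 1]; b <- idx[i]
      if ((profile[a] >= thr) && (profile[b] < thr)) {
        f <- (thr - profile[a]) / (profile[b] - profile[a])
        return(coords[a] + f * (coords[b] - coords[a]))
      }
    }
    NA_real_
  }
  right <- cross(p:length(profile))
  left <- cross(p:1)
  if (is.na(right) || is.na(left))
    stop("undefined width: profile never crosses the level", call. = FALSE)
  abs(right - left)
}

#' MSE between two beam reconstructions (display-domain protocol)
#'
#' Each intensity image is converted to decibels (`10 log10(I / max)`),
#' clipped to \[-60, 0\] dB, and median-filtered with a 5.5 x 5 wavelength
#' (axial x lateral) window so the comparison reflects the displayed beam
#' visualization rather than raw speckle; the mean squared pixel difference
#' of the two processed images is returned.
#'
#' @param recon_a,recon_b Intensity-kind `fus_image`s on a common grid.
#' @param wavelength Acoustic wavelength in meters.
#' @param median_kernel_wl Median window `c(axial, lateral)` in wavelengths
#'   (default 5.5 x 5).
#' @return Nonnegative scalar MSE (in squared dB; at most 3600 given the
#'   clip range).
#' @export
mse_protocol <- function(recon_a, recon_b, wavelength,
                         median_kernel_wl = c(5.5, 5)) {
  stopifnot(inherits(recon_a, "fus_image"), inherits(recon_b, "fus_image"))
  if (!same_grid(recon_a, recon_b)) stop("grid mismatch", call. = FALSE)
  proc <- function(img) {
    m <- max(img$values)
    if (m <= 0) stop("all-zero reconstruction", call. = FALSE)
    db <- 10 * log10(pmax(img$values / m, 1e-12))
    db <- pmin(pmax(db, -60), 0)
    dz <- img$z_grid[2] - img$z_grid[1]
    dx <- img$x_grid[2] - img$x_grid[1]
    k <- kernel_px(median_kernel_wl, wavelength, dz, dx)
    median_filter_cpp(db, k[1], k[2])
  }
  a <- proc(recon_a)
  b <- proc(recon_b)
  mean((a - b)^2)
}

#' Baseline-averaged MSE
#'
#' Arithmetic mean of [mse_protocol()] between a target reconstruction and
#' each of several baseline reconstructions from homogeneous regions.
#'
#' @param target Intensity `fus_image`.
#' @param baselines Nonempty list of intensity `fus_image`s.
#' @inheritParams mse_protocol
#' @return Mean MSE over the baselines.
#' @export
baseline_averaged_mse <- function(target, baselines, wavelength,
                                  median_kernel_wl = c(5.5, 5)) {
  if (length(baselines) < 1)
    stop("need at least one baseline", call. = FALSE)
  mean(vapply(baselines, function(b)
    mse_protocol(target, b, wavelength, median_kernel_wl), numeric(1)))
}

#' Mean MSE reduction achieved by normalization
#'
#' Given per-region MSE values before (`original`) and after (`normalized`)
#' echogenicity normalization, returns the mean of the pairwise differences
#' `original - normalized`.
#'
#' @param original,normalized Equal-length numeric vectors.
#' @return Mean reduction (positive when normalization helps).
#' @export
table_reduction <- function(original, normalized) {
  if (length(original) != length(normalized))
    stop("length mismatch", call. = FALSE)
  mean(original - normalized)
}

#' Format an MSE comparison table
#'
#' Plain-text table of per-region original/normalized MSE values with a
#' mean-reduction footer.
#'
#' @param regions Character vector of region names.
#' @param original,normalized Numeric vectors of MSE values.
#' @return Character vector of text lines (printed invisibly).
#' @export
format_mse_table <- function(regions, original, normalized) {
  stopifnot(length(regions) == length(original),
            length(original) == length(normalized))
  w <- max(nchar(c("Reconstruction", regions)))
  lines <- c(
    sprintf("%-*s  %10s  %10s", w, "Reconstruction", "Original",
            "Normalized"),
    sprintf("%-*s  %10.2f  %10.2f", w, regions, original, normalized),
    sprintf("%-*s  %10s  %10.2f", w, "Mean reduction", "",
            table_reduction(original, normalized)))
  cat(lines, sep = "\n")
  invisible(lines)
}
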