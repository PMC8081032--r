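#' Linear imaging array geometry
#'
#' Defines a 1-D linear array of point-like elements on the lateral (x) axis,
#' centered on x = 0, together with its center frequency, RF sampling rate and
#' the sound speed of the medium. Defaults describe a 128-element, 5 MHz probe
#' (0.3048 mm pitch, the L9-4/38 layout) sampled at four samples per
#' wavelength in a 1540 m/s medium.
#'
#' @param n_elements Number of elements (>= 2).
#' @param pitch Element spacing in meters.
#' @param f0 Center frequency in Hz.
#' @param fs RF sampling rate in Hz; must exceed 2 * `f0`.
#' @param c Sound speed in m/s.
#' @return An object of class `fus_array` with fields `n_elements`, `pitch`,
#'   `element_x` (element centers in meters, symmetric about 0), `f0`, `fs`,
#'   and `c`.
#' @examples
#' arr <- make_array()
#' diff(range(arr$element_x)) # 38.71 mm aperture
#' @export
make_array <- function(n_elements = 128L, pitch = 0.3048e-3, f0 = 5e6,
                       fs = 20e6, c = 1540) {
  n_elements <- as.integer(n_elements)
  if (is.na(n_elements) || n_elements < 2L)
    stop("invalid parameter: n_elements must be >= 2", call. = FALSE)
  for (nm in c("pitch", "f0", "fs", "c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("invalid parameter: ", nm, " must be a positive number",
           call. = FALSE)
  }
  if (fs < 2 * f0)
    stop("invalid parameter: fs must be at least 2 * f0 (aliasing)",
         call. = FALSE)
  element_x <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch
  structure(
    list(n_elements = n_elements, pitch = pitch, element_x = element_x,
         f0 = f0, fs = fs, c = c),
    class = "fus_array")
}

#' @export
print.fus_array <- function(x, ...) {
  cat(sprintf(
    "<fus_array> %d elements, pitch %.4g mm, aperture %.2f mm\n  f0 = %.3g MHz, fs = %.3g MHz (%.2g samples/wavelength), c = %g m/s\n",
    x$n_elements, x$pitch * 1e3, diff(range(x$element_x)) * 1e3,
    x$f0 / 1e6, x$fs / 1e6, x$fs / x$f0, x$c))
  invisible(x)
}

#' Wavelength of the array's center frequency
#'
#' @param array A `fus_array`.
#' @return c / f0 in meters.
#' @export
array_wavelength <- function(array) array$c / array$f0

#' Tone-burst pulse specification
#'
#' Builds a sampled tone burst of `n_cycles` cycles at `f0`, tapered by a
#' raised-cosine (Hann) or rectangular envelope. The waveform stands in for
#' the combined two-way electromechanical response of the transducer, i.e.
#' the band-limited wavelet each scatterer echoes back. The waveform is
#' referenced to its temporal center, so an echo's envelope peak falls at the
#' round-trip time of flight.
#'
#' @param n_cycles Number of carrier cycles (2 for the visualization pulse,
#'   25 for the mock therapy burst).
#' @param f0 Carrier frequency in Hz.
#' @param fs Sampling rate in Hz (must exceed 2 * f0).
#' @param window Envelope taper: `"hann"` (default) or `"rect"`.
#' @param amplitude Peak absolute amplitude of the sampled waveform.
#' @return Object of class `fus_pulse` with `waveform` (length `L =
#'   round(n_cycles * fs / f0)` samples), `L`, `duration = n_cycles / f0`,
#'   `center` (time from first sample to the waveform center, s), and the
#'   input parameters.
#' @examples
#' p <- make_pulse(2, 5e6, 20e6)
#' p$L # 8 samples
#' @export
make_pulse <- function(n_cycles = 2, f0 = 5e6, fs = 20e6,
                       window = c("hann", "rect"), amplitude = 1) {
  window <- match.arg(window)
  if (!is.numeric(n_cycles) || n_cycles < 1)
    stop("invalid parameter: n_cycles must be >= 1", call. = FALSE)
  if (fs <= 2 * f0)
    stop("aliasing: fs must exceed 2 * f0", call. = FALSE)
  L <- max(1L, as.integer(round(n_cycles * fs / f0)))
  n <- seq_len(L) - 1
  u <- n / fs
  uc <- (L - 1) / (2 * fs)
  env <- if (window == "hann" && L > 1) 0.5 * (1 - cos(2 * pi * n / (L - 1)))
         else rep(1, L)
  w <- env * cos(2 * pi * f0 * (u - uc))
  w <- w / max(abs(w)) * amplitude
  structure(
    list(waveform = w, L = L, duration = n_cycles / f0, center = uc,
         n_cycles = n_cycles, f0 = f0, fs = fs, window = window,
         amplitude = amplitude),
    class = "fus_pulse")
}

#' Transmit delays for a focused emission
#'
#' Computes per-element transmit delays so that all wavefronts arrive at the
#' focal point simultaneously. Delays are normalized so the earliest-firing
#' element fires at time zero; that firing defines the time origin shared by
#' the simulator and the beamformer.
#'
#' @param array A `fus_array`.
#' @param focus Focal point `c(x, z)` in meters, `z > 0`.
#' @return Object of class `fus_tx` with `kind = "focused"`, the `focus`, and
#'   per-element `delays` in seconds (min 0).
#' @examples
#' arr <- make_array()
#' tx <- focused_delays(arr, c(0, 30e-3))
#' range(tx$delays) * 1e6 # 0 to ~3.7 microseconds
#' @export
focused_delays <- function(array, focus) {
  stopifnot(inherits(array, "fus_array"))
  if (length(focus) != 2L || !all(is.finite(focus)) || focus[2] <= 0)
    stop("invalid geometry: focus must be c(x, z) with z > 0", call. = FALSE)
  d <- sqrt((array$element_x - focus[1])^2 + focus[2]^2)
  delays <- (max(d) - d) / array$c
  structure(
    list(kind = "focused", focus = focus, angle = NA_real_,
         delays = delays, t_ref = 0),
    class = "fus_tx")
}

#' Transmit delays for a steered plane wave
#'
#' Delays are affine in element position with slope `sin(angle)/c`, shifted
#' so the earliest element fires at time zero. `t_ref` records that shift so
#' beamformers can reconstruct the absolute wavefront timing: the transmit
#' wavefront reaches a point (x, z) at time
#' `(x * sin(angle) + z * cos(angle)) / c + t_ref`.
#'
#' @param array A `fus_array`.
#' @param angle Steering angle in radians, |angle| < pi/2. Positive angles
#'   steer toward positive x.
#' @return Object of class `fus_tx` with `kind = "plane_wave"`.
#' @export
plane_wave_delays <- function(array, angle) {
  stopifnot(inherits(array, "fus_array"))
  if (!is.finite(angle) || abs(angle) >= pi / 2)
    stop("invalid parameter: |angle| must be < 90 degrees", call. = FALSE)
  raw <- array$element_x * sin(angle) / array$c
  structure(
    list(kind = "plane_wave", focus = NULL, angle = angle,
         delays = raw - min(raw), t_ref = -min(raw)),
    class = "fus_tx")
}

#' Time-of-flight receive delay for delay-and-sum focusing
#'
#' The full two-way delay for an image point at depth `z` on the line at
#' `x_c`, received by an element at `x`: the transmit part `tau_F + z / c`
#' (the focusing delay applied to the line's element plus the downward travel
#' time) plus the receive path `sqrt(z^2 + (x - x_c)^2) / c`.
#'
#' @param x Receive element lateral position (m).
#' @param x_c Image line lateral position (m).
#' @param z Depth (m), > 0.
#' @param c Sound speed (m/s).
#' @param tau_F Transmit focusing delay of the line's element (s).
#' @return Delay in seconds: `tau_F + (z + sqrt(z^2 + (x - x_c)^2)) / c`.
#' @export
receive_delay <- function(x, x_c, z, c, tau_F = 0) {
  if (any(z <= 0)) stop("invalid depth: z must be > 0", call. = FALSE)
  tau_F + (z + sqrt(z^2 + (x - x_c)^2)) / c
}
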