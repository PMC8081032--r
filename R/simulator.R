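#' Simulator options
#'
#' Controls the idealized element model of the RF forward simulator: optional
#' 1/r geometric spreading per propagation path, an optional hard-baffle
#' cosine directivity factor per path, and additive white sensor noise.
#'
#' @param spreading `"1/r"` (default) applies 1/r amplitude decay on each of
#'   the transmit and receive paths; `"none"` disables it.
#' @param directivity `"none"` (default) or `"cosine"` (multiplies each path
#'   by the cosine of the angle from the element normal).
#' @param noise_rms Additive white Gaussian sensor noise RMS (linear units,
#'   >= 0; default 0).
#' @export
sim_options <- function(spreading = c("1/r", "none"),
                        directivity = c("none", "cosine"), noise_rms = 0) {
  spreading <- match.arg(spreading)
  directivity <- match.arg(directivity)
  if (noise_rms < 0) stop("noise_rms must be >= 0", call. = FALSE)
  structure(list(spreading = spreading, directivity = directivity,
                 noise_rms = noise_rms), class = "fus_sim_options")
}

#' Simulate per-channel RF data for one transmit event
#'
#' Point-scatterer forward model: every active transmit element insonifies
#' every scatterer, and every scatterer echoes a band-limited wavelet back to
#' every receive element. Sample `t` of channel `j` accumulates
#' `A_k * g_tx * g_rx * w(t - delay_e - (d_ek + d_kj)/c)` over transmit
#' elements `e` and scatterers `k`, with `w` the two-way wavelet (referenced
#' to its center), `d` Euclidean distances and `g` the optional spreading /
#' directivity factors. Subsample delays are realized by linear
#' interpolation of `w`. The model is linear in scatterer amplitudes and
#' contains no multiple scattering, nonlinearity, or attenuation.
#'
#' @param array A `fus_array`.
#' @param tx A `fus_tx` transmit event.
#' @param pulse A `fus_pulse` (the two-way wavelet).
#' @param scene A `fus_scene` (may be empty).
#' @param opts A `fus_sim_options`.
#' @param seed Integer seed for the sensor noise (only drawn when
#'   `noise_rms > 0`).
#' @param t_max Record length in seconds. Default covers the farthest
#'   round trip plus the pulse: `max(delays) + 2 * d_max / c + duration`.
#'   A user-supplied window too short for the scene triggers a truncation
#'   warning and sets the `truncated` attribute.
#' @param tx_elements Indices of transmitting elements (default: all).
#' @return Object of class `fus_rf`: `data` (matrix `n_samples x
#'   n_elements`), `fs`, `t0`, `tx`, `array`, `pulse`.
#' @export
simulate_rf <- function(array, tx, pulse, scene, opts = sim_options(),
                        seed = 1L, t_max = NULL, tx_elements = NULL) {
  stopifnot(inherits(array, "fus_array"), inherits(tx, "fus_tx"),
            inherits(pulse, "fus_pulse"), inherits(scene, "fus_scene"))
  if (length(scene$amplitude) && any(!is.finite(scene$amplitude)))
    stop("scene has non-finite amplitudes", call. = FALSE)
  if (is.null(tx_elements)) tx_elements <- seq_len(array$n_elements)
  t0 <- 0
  nk <- length(scene$x)
  needed <- if (nk > 0) {
    dmax <- max(sqrt(outer(scene$x, range(array$element_x), "-")^2 +
                       scene$z^2))
    max(tx$delays[tx_elements]) + 2 * dmax / array$c + pulse$duration
  } else pulse$duration
  # default window adds ~5 mm of depth margin so beamforming grids that
  # slightly overreach the scene stay inside the record
  pad <- 2 * 5e-3 / array$c
  truncated <- FALSE
  if (is.null(t_max)) {
    t_max <- needed + pad
  } else if (t_max < needed && nk > 0) {
    truncated <- TRUE
    warning("record window shorter than farthest echo; frame truncated",
            call. = FALSE)
  }
  n_samples <- as.integer(ceiling(t_max * array$fs)) + 1L
  data <- rf_forward_cpp(array$element_x, tx$delays,
                         as.integer(tx_elements) - 1L,
                         scene$x, scene$z, scene$amplitude,
                         pulse$waveform, pulse$center, array$fs, t0,
                         n_samples, scene$c, opts$spreading == "1/r",
                         opts$directivity == "cosine")
  if (opts$noise_rms > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(as.integer(seed))
    data <- data + matrix(stats::rnorm(length(data), 0, opts$noise_rms),
                          nrow = nrow(data))
  }
  structure(
    list(data = data, fs = array$fs, t0 = t0, tx = tx, array = array,
         pulse = pulse, truncated = truncated),
    class = "fus_rf")
}

#' Simulate the full beam-visualization acquisition sequence
#'
#' Emulates one capture of the interleaved excitation sequence: a mock
#' therapy tone burst (logged but producing no frame used downstream), one
#' short focused visualization transmit, and a series of steered plane-wave
#' transmits for B-mode formation — all over the same scene.
#'
#' @param array A `fus_array`.
#' @param scene A `fus_scene`.
#' @param config A `fus_config` (see [recon_config()]) naming the FUS focus,
#'   plane-wave angles and pulse lengths.
#' @param seed Integer seed; per-frame noise seeds are derived from it.
#' @param opts A `fus_sim_options`.
#' @return Object of class `fus_acquisition`: `visualization` (one `fus_rf`),
#'   `bmode` (list of `fus_rf`, one per angle), and `sequence_log`
#'   (data frame of all transmit events including the mock therapy burst).
#' @export
simulate_acquisition <- function(array, scene, config = recon_config(),
                                 seed = 1L, opts = sim_options()) {
  stopifnot(inherits(config, "fus_config"))
  seed <- as.integer(seed)
  pulse_vis <- make_pulse(config$n_cycles_vis, array$f0, array$fs)
  tx_f <- focused_delays(array, config$fus_focus)
  vis <- simulate_rf(array, tx_f, pulse_vis, scene, opts, seed = seed + 1L)
  bmode <- vector("list", length(config$pw_angles))
  for (i in seq_along(config$pw_angles)) {
    tx_pw <- plane_wave_delays(array, config$pw_angles[i])
    bmode[[i]] <- simulate_rf(array, tx_pw, pulse_vis, scene, opts,
                              seed = seed + 1L + i)
  }
  log <- data.frame(
    event = seq_len(2L + length(config$pw_angles)),
    kind = c("therapy_burst", "focused_visualization",
             rep("plane_wave", length(config$pw_angles))),
    n_cycles = c(config$n_cycles_therapy, config$n_cycles_vis,
                 rep(config$n_cycles_vis, length(config$pw_angles))),
    angle_deg = c(NA, NA, config$pw_angles * 180 / pi),
    produces_frame = c(FALSE, TRUE, rep(TRUE, length(config$pw_angles))))
  structure(list(visualization = vis, bmode = bmode, sequence_log = log,
                 config = config, seed = seed),
            class = "fus_acquisition")
}

#' @export
print.fus_acquisition <- function(x, ...) {
  cat(sprintf("<fus_acquisition> %d frames (1 focused + %d plane waves)\n",
              1L + length(x$bmode), length(x$bmode)))
  print(x$sequence_log)
  invisible(x)
}
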