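# Independent oracles coded from first principles, kept deliberately naive:
# plain loops, no shared code with the package internals.

# Naive delay-and-sum with dynamic aperture, Hanning apodization and CF.
# rf: n_t x n_e matrix; tau_f: per-line transmit delay (length(x_grid)).
oracle_das <- function(rf, fs, t0, element_x, x_grid, z_grid, tau_f, c,
                       f_number) {
  nt <- nrow(rf)
  y <- matrix(0, length(z_grid), length(x_grid))
  cf <- matrix(0, length(z_grid), length(x_grid))
  for (ix in seq_along(x_grid)) {
    xc <- x_grid[ix]
    for (iz in seq_along(z_grid)) {
      z <- z_grid[iz]
      half <- z / (2 * f_number)
      vals <- c()
      for (e in seq_along(element_x)) {
        dx <- element_x[e] - xc
        if (abs(dx) > half) next
        w <- if (half > 0) 0.5 * (1 + cos(pi * dx / half)) else 1
        tau <- tau_f[ix] + (z + sqrt(z^2 + dx^2)) / c
        s <- (tau - t0) * fs
        i0 <- floor(s)
        v <- if (i0 >= 0 && i0 + 1 <= nt - 1) {
          f <- s - i0
          (1 - f) * rf[i0 + 1, e] + f * rf[i0 + 2, e]
        } else 0
        vals <- c(vals, w * v)
      }
      y[iz, ix] <- sum(vals)
      denom <- length(vals) * sum(vals^2)
      cf[iz, ix] <- if (length(vals) && denom > 0) sum(vals)^2 / denom else 0
    }
  }
  list(y = y, cf = cf)
}

# Time of flight of the echo from scatterer (sx, sz) fired by element e and
# received by element j, in samples from t0 (0-based).
oracle_echo_sample <- function(element_x, tx_delay_e, e, j, sx, sz, c, fs,
                               t0 = 0) {
  d_e <- sqrt((sx - element_x[e])^2 + sz^2)
  d_j <- sqrt((sx - element_x[j])^2 + sz^2)
  (tx_delay_e + (d_e + d_j) / c - t0) * fs
}

# A scene holding arbitrary point scatterers (positive amplitudes).
point_scene <- function(x, z, amp = rep(1, length(x)), c = 1540) {
  pts <- Map(function(xi, zi, ai) point_target(xi, zi, 20 * log10(ai)),
             x, z, amp)
  build_scene(scene_spec(c = c, points = pts), seed = 1)
}

img_db10 <- function(img) {
  10 * log10(pmax(img$values / max(img$values), 1e-30))
}
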