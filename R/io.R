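#' Save / load RF frame containers
#'
#' Acquisitions are stored as single-file RDS containers carrying the RF
#' matrices with their sampling metadata, the transmit events, the scene
#' seed, and a configuration hash. A matching loader restores the
#' `fus_acquisition`.
#'
#' @param acq A `fus_acquisition`.
#' @param path Output file path.
#' @return `save_frames` returns `path` invisibly; `load_frames` returns the
#'   `fus_acquisition`.
#' @export
save_frames <- function(acq, path) {
  stopifnot(inherits(acq, "fus_acquisition"))
  saveRDS(acq, path)
  invisible(path)
}

#' @rdname save_frames
#' @export
load_frames <- function(path) {
  if (!file.exists(path)) stop("no such RF container: ", path, call. = FALSE)
  acq <- readRDS(path)
  if (!inherits(acq, "fus_acquisition"))
    stop("malformed RF container: ", path, call. = FALSE)
  acq
}

#' Export a beamformed image to CSV
#'
#' Plain-text interchange: the value matrix with the grids in a small JSON
#' sidecar (`<path>.meta.json`).
#'
#' @param img A `fus_image`.
#' @param path CSV output path.
#' @export
write_image_csv <- function(img, path) {
  stopifnot(inherits(img, "fus_image"))
  utils::write.table(img$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(kind = img$kind, x_grid = img$x_grid, z_grid = img$z_grid),
    paste0(path, ".meta.json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_image_csv
#' @export
read_image_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  v <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(v) <- NULL
  beamformed_image(v, meta$x_grid, meta$z_grid, meta$kind)
}

#' Deterministic hash of a configuration object
#'
#' MD5 of the serialized object, used to stamp output artifacts so two runs
#' with identical configuration are identifiable.
#'
#' @param x Any R object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Read / write run configurations
#'
#' Run configurations are YAML (JSON also accepted) files with `probe`,
#' `scene`, `recon` and `run` sections; see
#' `system.file("extdata", "demo_config.yaml", package = "fusbeam")` for the
#' schema. Units are SI (meters, Hz, seconds).
#'
#' @param path Path to a YAML or JSON config file.
#' @return A named list with class `fus_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  for (sec in c("scene", "run"))
    if (is.null(cfg[[sec]]))
      stop("config is missing the '", sec, "' section", call. = FALSE)
  class(cfg) <- "fus_run_config"
  cfg
}

config_to_objects <- function(cfg) {
  p <- cfg$probe
  array <- make_array(
    n_elements = p$n_elements %||% 128L, pitch = p$pitch %||% 0.3048e-3,
    f0 = p$f0 %||% 5e6, fs = p$fs %||% 20e6,
    c = cfg$scene$c %||% (p$c %||% 1540))
  s <- cfg$scene
  regions <- lapply(s$regions, function(r)
    region_disk(unlist(r$center), r$radius, r$offset_db,
                r$label %||% "disk"))
  points <- lapply(s$points, function(q)
    point_target(q$x, q$z, q$boost_db %||% 40, q$label %||% "point"))
  spec <- scene_spec(
    x_range = if (!is.null(s$x_range)) unlist(s$x_range),
    z_range = if (!is.null(s$z_range)) unlist(s$z_range),
    density_per_cell = s$density_per_cell %||% 15,
    sigma = s$sigma %||% 1, c = s$c %||% 1540, f0 = array$f0,
    regions = regions, points = points)
  r <- cfg$recon %||% list()
  config <- recon_config(
    fus_focus = unlist(r$fus_focus %||% c(0, 30e-3)),
    pw_angles = (unlist(r$pw_angles_deg %||% seq(-18, 18, 6))) * pi / 180,
    rx_f_number = r$rx_f_number %||% 1,
    gate_db = r$gate_db %||% -60,
    overlay_threshold = r$overlay_threshold %||% -20)
  opts <- sim_options(noise_rms = cfg$scene$noise_rms %||% 0)
  list(array = array, spec = spec, config = config, opts = opts,
       seed = as.integer(cfg$run$seed %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
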