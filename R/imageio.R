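# Calibrated image containers, TIFF + JSON sidecar I/O, study manifests and
# pipeline configuration.

CHANNEL_ROLES <- c("glut4", "dystrophin", "mhc1", "dapi", "dhpr")
MANDATORY_ROLES <- c("glut4", "dystrophin")
INTENSITY_MAX <- 65535  # images are stored as 16-bit TIFF pages

#' Calibrated multi-channel image
#'
#' Container for a single-fibre multi-channel fluorescence image: a named list
#' of 2D intensity matrices (one per channel role) plus the pixel size in
#' micrometres per pixel. Matrices are indexed `[x, y]` with 1-based pixel
#' centres. Intensities are arbitrary units in `[0, 65535]` (16-bit range).
#'
#' @param channels named list of numeric matrices. Names must be channel
#'   roles from `glut4`, `dystrophin`, `mhc1`, `dapi`, `dhpr`; `glut4` and
#'   `dystrophin` are mandatory. All matrices must share dimensions.
#' @param pixel_size pixel size, micrometres per pixel (> 0).
#' @param image_id identifier string.
#' @return object of class `calibrated_image`.
#' @export
calibrated_image <- function(channels, pixel_size, image_id = "image") {
  if (!is.list(channels) || is.null(names(channels))) {
    abort_glut4("`channels` must be a named list of matrices",
                "glut4_format_error")
  }
  bad <- setdiff(names(channels), CHANNEL_ROLES)
  if (length(bad)) {
    abort_glut4(paste0("unknown channel role(s): ", paste(bad, collapse = ", ")),
                "glut4_role_error")
  }
  missing <- setdiff(MANDATORY_ROLES, names(channels))
  if (length(missing)) {
    abort_glut4(paste0("missing mandatory channel role(s): ",
                       paste(missing, collapse = ", ")), "glut4_role_error")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1)))) {
    abort_glut4("all channels must be 2D matrices", "glut4_format_error")
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    abort_glut4("all channels must share identical dimensions",
                "glut4_format_error")
  }
  stopifnot_scalar_number(pixel_size, "pixel_size", positive = TRUE)
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    abort_glut4("intensities must be non-negative", "glut4_format_error")
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 image_id = as.character(image_id)),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<calibrated_image> %s: %dx%d px, %.4g um/px, channels: %s\n",
              x$image_id, d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Write a calibrated image as multi-page TIFF plus JSON sidecar
#'
#' One 16-bit TIFF page per channel, channel order and pixel size recorded in
#' a JSON sidecar next to the image. Integer intensities in `[0, 65535]`
#' round-trip bit-exactly through [read_image()].
#'
#' @param img a `calibrated_image`.
#' @param path output TIFF path.
#' @param sidecar sidecar JSON path (default `paste0(path, ".json")`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(img, "calibrated_image"))
  pages <- lapply(img$channels, function(m) {
    if (any(m > INTENSITY_MAX)) {
      warn_glut4("intensities clipped to 16-bit range on write",
                 "glut4_clip_warning")
      m <- pmin(m, INTENSITY_MAX)
    }
    t(m) / INTENSITY_MAX  # tiff stores [row = y, col = x]
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(image_id = img$image_id, pixel_size_um = img$pixel_size,
               channels = names(img$channels))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated image from multi-page TIFF plus JSON sidecar
#'
#' @param path TIFF path.
#' @param sidecar sidecar JSON declaring `channels` (page order) and
#'   `pixel_size_um`.
#' @return a [calibrated_image()].
#' @export
read_image <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) {
    abort_glut4(paste0("image file not found: ", path), "glut4_io_error")
  }
  if (!file.exists(sidecar)) {
    abort_glut4(paste0("sidecar not found: ", sidecar), "glut4_calibration_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$pixel_size_um)) {
    abort_glut4("sidecar lacks pixel_size_um", "glut4_calibration_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(meta$channels)) {
    abort_glut4("sidecar channel count does not match TIFF page count",
                "glut4_format_error")
  }
  shp <- vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"), character(1))
  if (length(unique(shp)) != 1L) {
    abort_glut4("TIFF pages differ in shape", "glut4_format_error")
  }
  channels <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate grey-stored-as-RGB
    m <- round(t(p) * INTENSITY_MAX)
    storage.mode(m) <- "integer"  # 16-bit data: exact integer round trip
    m
  })
  names(channels) <- meta$channels
  calibrated_image(channels, meta$pixel_size_um,
                   image_id = meta$image_id %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Pipeline configuration

config_defaults <- function() {
  list(
    band_halfwidth_px = 2.5,     # PM band halfwidth about the midline (5 px total)
    n_layers = 20L,              # concentric intracellular layers
    layer_thickness_um = 1.0,
    spot_intensity_threshold = 4500,  # a.u., on the filtered detection channel
    spot_min_area_px = 4L,
    size_class_boundary_um = 1.0,
    snake_alpha = 0.05,          # contour tension
    snake_beta = 2.0,            # contour rigidity
    snake_sigma_px = 2.0,        # smoothing of the external energy image
    snake_step = 0.5,            # time step of the semi-implicit update
    snake_kappa = 4.0,           # external force weight
    snake_edge_weight = 0.0,     # weight of the |grad|^2 edge functional
    snake_line_weight = 1.0,     # weight of the bright-line (ridge) functional
    snake_max_iter = 2000L,
    snake_tol_px = 0.05,
    snake_n_vertices = 120L,
    pre_background_sigma_px = 10,  # no-neighbour background estimate
    pre_background_weight = 0.9,
    pre_highpass_sigma_px = 2,     # HiGauss high-pass scale
    pre_highpass_gain = 2,
    min_object_area_px = 200L,     # initialisation: smallest fibre accepted
    alpha = 0.05                   # significance level for the statistics stage
  )
}

#' Build a pipeline configuration
#'
#' All keys default to the study constants (PM band halfwidth 2.5 px, twenty
#' 1 um layers, 1 um large/small class boundary) or to fixture-stable
#' processing parameters. Each key carries a provenance flag (`default` or
#' `user`) in the `provenance` attribute.
#'
#' @param ... named overrides of default keys.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  defs <- config_defaults()
  bad <- setdiff(names(over), names(defs))
  if (length(bad)) {
    abort_glut4(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
                "glut4_config_error")
  }
  cfg <- utils::modifyList(defs, over)
  prov <- ifelse(names(cfg) %in% names(over), "user", "default")
  names(prov) <- names(cfg)
  cfg <- structure(cfg, class = "pipeline_config", provenance = prov)
  viol <- validate_config(cfg)
  if (length(viol)) {
    abort_glut4(paste0("invalid configuration:\n  - ",
                       paste(viol, collapse = "\n  - ")), "glut4_config_error")
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a `pipeline_config` or plain named list.
#' @return character vector of violations; `character(0)` when valid.
#' @export
validate_config <- function(cfg) {
  v <- character(0)
  nonneg <- c("band_halfwidth_px", "spot_intensity_threshold",
              "spot_min_area_px", "size_class_boundary_um",
              "snake_sigma_px", "snake_tol_px", "pre_background_sigma_px",
              "pre_highpass_sigma_px", "pre_highpass_gain")
  for (k in nonneg) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] < 0) {
      v <- c(v, sprintf("%s must be a non-negative scalar", k))
    }
  }
  if (!is.numeric(cfg$n_layers) || cfg$n_layers < 1) {
    v <- c(v, "n_layers must be >= 1")
  }
  if (!is.numeric(cfg$layer_thickness_um) || cfg$layer_thickness_um <= 0) {
    v <- c(v, "layer_thickness_um must be > 0")
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    v <- c(v, "alpha must lie in (0, 1)")
  }
  v
}

#' Load a pipeline configuration from a YAML file
#'
#' Unspecified keys take the package defaults; the fully resolved
#' configuration (with per-key provenance) is logged to stderr.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param quiet suppress the resolved-config log.
#' @return a [pipeline_config()].
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  over <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort_glut4(paste0("config file not found: ", path), "glut4_io_error")
    }
    over <- yaml::read_yaml(path)
    if (is.null(over)) over <- list()
  }
  cfg <- pipeline_config(over)
  if (!quiet) log_resolved_config(cfg)
  cfg
}

log_resolved_config <- function(cfg) {
  prov <- attr(cfg, "provenance")
  for (k in names(unclass(cfg))) {
    message(sprintf("config: %-26s = %-8s [%s]", k,
                    paste(format(cfg[[k]]), collapse = ","), prov[[k]]))
  }
  invisible(cfg)
}

# ---------------------------------------------------------------------------
# Study manifest

MANIFEST_COLS <- c("subject_id", "mode", "timepoint", "replicate",
                   "fibre_index", "fibre_type", "image_path")

#' Read / write a study manifest CSV
#'
#' The manifest links every image to its design cell: columns `subject_id`,
#' `mode` (ET/SIT), `timepoint` (pre/post), `replicate`, `fibre_index`,
#' `fibre_type` (I/II), `image_path`.
#'
#' @param path CSV path.
#' @return data.frame with the manifest columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort_glut4(paste0("manifest not found: ", path), "glut4_io_error")
  }
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(MANIFEST_COLS, names(man))
  if (length(missing)) {
    abort_glut4(paste0("manifest lacks column(s): ",
                       paste(missing, collapse = ", ")), "glut4_format_error")
  }
  man
}

#' @rdname read_manifest
#' @param manifest data.frame to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
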