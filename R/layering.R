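# Concentric layer construction from the Euclidean distance map of the
# intracellular mask: the PM band is layer 0; layers 1..n are 1 um shells
# measured inward from the inner edge of the PM band; deeper pixels form the
# core.

#' Euclidean distance map of the intracellular region
#'
#' For every intracellular pixel, the Euclidean distance (micrometres) to
#' the nearest non-intracellular pixel centre, i.e. the depth from the inner
#' edge of the PM band. Band and exterior pixels carry `NA`.
#'
#' @param roi a `fibre_roi` from [make_masks()].
#' @return numeric matrix of distances (um), `NA` outside the intracellular
#'   mask.
#' @export
distance_map <- function(roi) {
  stopifnot(inherits(roi, "fibre_roi"))
  m <- roi$intracellular_mask
  if (!any(m)) {
    abort_glut4("empty intracellular mask", "glut4_degenerate_fibre")
  }
  d <- as.matrix(EBImage::distmap(matrix(as.numeric(m), nrow(m), ncol(m))))
  out <- d * roi$pixel_size
  out[!m] <- NA_real_
  out
}

#' Build the PM layer and concentric intracellular layers
#'
#' Layer `k` (k = 1..n) holds the intracellular pixels at depth `d` with
#' `(k-1) * thickness < d <= k * thickness` (half-open shells, boundary
#' assigned inward); pixels deeper than `n * thickness` form the core. Empty
#' trailing layers are emitted flagged incomplete. A layer is complete when
#' it is non-empty and fully separates the deeper region from the shallower
#' one (vacuously when nothing lies deeper).
#'
#' @param roi a `fibre_roi`.
#' @param n_layers number of 1 um shells (default 20).
#' @param thickness_um shell thickness, micrometres.
#' @return a `layer_set`: list with `pm_layer` (mask, index 0),
#'   `intracellular_layers` (list of masks, index 1..n), `core_mask`,
#'   `layer_areas_um2` (named vector over pm/1..n/core),
#'   `complete_flags`, `pixel_size`.
#' @export
build_layers <- function(roi, n_layers = 20L, thickness_um = 1.0) {
  stopifnot(inherits(roi, "fibre_roi"))
  if (n_layers < 1) abort_glut4("n_layers must be >= 1", "glut4_config_error")
  d <- distance_map(roi)
  ps2 <- roi$pixel_size^2
  layers <- vector("list", n_layers)
  complete <- logical(n_layers)
  intra <- roi$intracellular_mask
  for (k in seq_len(n_layers)) {
    lk <- intra & !is.na(d) & d > (k - 1) * thickness_um & d <= k * thickness_um
    layers[[k]] <- lk
    inner <- intra & !is.na(d) & d > k * thickness_um
    if (!any(lk)) {
      complete[k] <- FALSE
    } else if (!any(inner)) {
      complete[k] <- TRUE  # central cap: nothing deeper to enclose
    } else {
      outer <- intra & !is.na(d) & d <= (k - 1) * thickness_um
      outer <- outer | roi$pm_band_mask | !(intra | roi$pm_band_mask)
      complete[k] <- !masks_touch(inner, outer)
    }
  }
  core <- intra & !is.na(d) & d > n_layers * thickness_um
  areas <- c(sum(roi$pm_band_mask),
             vapply(layers, sum, numeric(1)), sum(core)) * ps2
  names(areas) <- c("pm", as.character(seq_len(n_layers)), "core")
  structure(list(
    pm_layer = roi$pm_band_mask, intracellular_layers = layers,
    core_mask = core, layer_areas_um2 = areas, complete_flags = complete,
    n_layers = as.integer(n_layers), thickness_um = thickness_um,
    pixel_size = roi$pixel_size
  ), class = "layer_set")
}

# TRUE if any pixel of a is 4-adjacent to (or coincides with) a pixel of b
masks_touch <- function(a, b) {
  if (any(a & b)) return(TRUE)
  nx <- nrow(a); ny <- ncol(a)
  any(a[-nx, ] & b[-1, ]) || any(a[-1, ] & b[-nx, ]) ||
    any(a[, -ny] & b[, -1]) || any(a[, -1] & b[, -ny])
}

#' Area of a layer mask in square micrometres
#'
#' @param mask logical matrix.
#' @param pixel_size micrometres per pixel.
#' @return pixel count times `pixel_size^2`; `0` with a warning for an empty
#'   mask (densities over it are undefined).
#' @export
layer_area <- function(mask, pixel_size) {
  n <- sum(mask)
  if (n == 0) {
    warn_glut4("empty layer mask: area 0, densities undefined",
               "glut4_empty_layer")
  }
  n * pixel_size^2
}

#' Label matrix of a layer set
#'
#' Integer-coded image: 0 = exterior, 1 = PM band, `1 + k` = layer k,
#' `n_layers + 2` = core. Useful for export and for centroid-based spot
#' assignment.
#' @param layers a `layer_set`.
#' @return integer matrix.
#' @export
layer_label_matrix <- function(layers) {
  lab <- matrix(0L, nrow(layers$pm_layer), ncol(layers$pm_layer))
  lab[layers$pm_layer] <- 1L
  for (k in seq_len(layers$n_layers)) {
    lab[layers$intracellular_layers[[k]]] <- 1L + k
  }
  lab[layers$core_mask] <- layers$n_layers + 2L
  lab
}
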