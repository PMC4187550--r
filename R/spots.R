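# GLUT4 spot detection: detection-channel preprocessing (background
# subtraction + high-pass enhancement), uniform-threshold connected-component
# detection, equivalent-diameter size classification and layer assignment.
#
# The filtered channel is used for detection only; intensity metrics always
# run on the raw channel (enforced by a class tag on the filtered matrix).

#' Preprocess the GLUT4 channel for spot detection
#'
#' Two stages. (1) No-neighbour background subtraction:
#' `F1 = max(I - w * G_sb(I), 0)` where `G_sb` is a wide Gaussian estimating
#' out-of-focus background (sigma `pre_background_sigma_px`, weight
#' `pre_background_weight`). (2) High-pass Gaussian ("HiGauss") enhancement:
#' `F2 = max(F1 + g * (F1 - G_sh(F1)), 0)`. The output is tagged
#' `glut4_filtered` and is rejected by the intensity metrics, which operate
#' on raw data only.
#'
#' @param glut4 raw GLUT4 channel, numeric matrix.
#' @param cfg a [pipeline_config()].
#' @return filtered matrix with class attribute `glut4_filtered`.
#' @export
preprocess_glut4 <- function(glut4, cfg = pipeline_config()) {
  f1 <- pmax(glut4 - cfg$pre_background_weight *
               gauss_blur(glut4, cfg$pre_background_sigma_px), 0)
  f2 <- pmax(f1 + cfg$pre_highpass_gain *
               (f1 - gauss_blur(f1, cfg$pre_highpass_sigma_px)), 0)
  structure(f2, class = c("glut4_filtered", class(f2)))
}

#' Detect GLUT4 spots by uniform intensity and size thresholds
#'
#' Thresholds the filtered channel at `intensity_threshold` within
#' `region_mask`, labels 8-connected components, discards components smaller
#' than `min_area_px`, and summarises each survivor as a spot with
#' intensity-weighted centroid, area, equivalent diameter, size class and
#' peak (filtered) intensity. Zero spots is a valid outcome.
#'
#' @param filtered output of [preprocess_glut4()] (or any detection channel).
#' @param region_mask logical matrix restricting detection.
#' @param intensity_threshold uniform threshold, a.u. (>= 0).
#' @param min_area_px minimum component pixel count.
#' @param pixel_size micrometres per pixel.
#' @param boundary_um large/small class boundary, micrometres.
#' @param fibre_id identifier recorded in the result.
#' @return a `spot_set`: list with `fibre_id`, `spots` (data.frame: x, y,
#'   area_px, area_um2, eq_diam_um, class, peak_intensity, layer_index NA
#'   until [assign_layers()]) and `params`.
#' @export
detect_spots <- function(filtered, region_mask, intensity_threshold,
                         min_area_px = 4L, pixel_size = 0.2,
                         boundary_um = 1.0, fibre_id = "fibre") {
  if (intensity_threshold < 0) {
    abort_glut4("intensity_threshold must be >= 0", "glut4_invalid_parameter")
  }
  bin <- unclass(filtered) >= intensity_threshold & region_mask
  lab <- label8(bin)
  spots <- empty_spot_df()
  if (max(lab) > 0) {
    px <- which(lab > 0)
    ids <- lab[px]
    sizes <- tabulate(ids, nbins = max(lab))
    keep <- which(sizes >= min_area_px)
    if (length(keep)) {
      xi <- (px - 1) %% nrow(lab) + 1
      yi <- (px - 1) %/% nrow(lab) + 1
      wt <- unclass(filtered)[px]
      rows <- lapply(keep, function(id) {
        sel <- ids == id
        w <- wt[sel]
        area_px <- sizes[id]
        area_um2 <- area_px * pixel_size^2
        data.frame(
          x = sum(xi[sel] * w) / sum(w), y = sum(yi[sel] * w) / sum(w),
          area_px = area_px, area_um2 = area_um2,
          eq_diam_um = equivalent_diameter(area_um2),
          peak_intensity = max(w), stringsAsFactors = FALSE
        )
      })
      spots <- do.call(rbind, rows)
      spots$class <- vapply(spots$eq_diam_um, classify_spot, character(1),
                            boundary_um = boundary_um)
      spots$layer_index <- NA_integer_
    }
  }
  structure(list(
    fibre_id = fibre_id, spots = spots,
    params = list(intensity_threshold = intensity_threshold,
                  min_area_px = min_area_px, pixel_size = pixel_size,
                  boundary_um = boundary_um)
  ), class = "spot_set")
}

empty_spot_df <- function() {
  data.frame(x = numeric(0), y = numeric(0), area_px = numeric(0),
             area_um2 = numeric(0), eq_diam_um = numeric(0),
             peak_intensity = numeric(0), class = character(0),
             layer_index = integer(0), stringsAsFactors = FALSE)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a union-find pass over the label adjacency.
label8 <- function(bin) {
  lab <- as.matrix(EBImage::bwlabel(matrix(as.numeric(bin), nrow(bin), ncol(bin))))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  nx <- nrow(lab); ny <- ncol(lab)
  pair_merge <- function(a, b) {
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) {
      pr <- unique(cbind(a[sel], b[sel]))
      for (r in seq_len(nrow(pr))) unite(pr[r, 1], pr[r, 2])
    }
  }
  # diagonal neighbours (4-adjacency already shares labels)
  pair_merge(lab[-nx, -ny], lab[-1, -1])
  pair_merge(lab[-nx, -1], lab[-1, -ny])
  root <- vapply(seq_len(nlab), find, integer(1))
  # compact to 1..k
  root <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- root[lab[lab > 0]]
  out
}

#' Equivalent diameter of a spot
#'
#' Diameter of the circle with the spot's area: `2 * sqrt(area / pi)`.
#' @param area_um2 spot area, square micrometres (> 0).
#' @return diameter in micrometres.
#' @export
equivalent_diameter <- function(area_um2) {
  if (any(!is.finite(area_um2)) || any(area_um2 <= 0)) {
    abort_glut4("spot area must be > 0", "glut4_invalid_spot")
  }
  2 * sqrt(area_um2 / pi)
}

#' Classify a spot as large or small by its equivalent diameter
#'
#' Diameter at or above the boundary (default 1 um) is `large`, below is
#' `small`; the boundary itself is assigned to `large` as the documented
#' deterministic tie-break.
#' @param diameter_um equivalent diameter, micrometres (> 0).
#' @param boundary_um class boundary, micrometres.
#' @return `"large"` or `"small"`.
#' @export
classify_spot <- function(diameter_um, boundary_um = 1.0) {
  if (!is.finite(diameter_um) || diameter_um <= 0) {
    abort_glut4("spot diameter must be > 0", "glut4_invalid_spot")
  }
  if (diameter_um >= boundary_um) "large" else "small"
}

#' Assign detected spots to layers by centroid
#'
#' Each spot inherits the layer containing its centroid pixel: 0 for the PM
#' band, 1..n for the concentric shells, `n_layers + 1` for the core.
#'
#' @param spotset a `spot_set`.
#' @param layers a `layer_set`.
#' @return the `spot_set` with `layer_index` filled.
#' @export
assign_layers <- function(spotset, layers) {
  stopifnot(inherits(spotset, "spot_set"), inherits(layers, "layer_set"))
  if (nrow(spotset$spots) == 0) return(spotset)
  lab <- layer_label_matrix(layers)
  px <- round(spotset$spots$x); py <- round(spotset$spots$y)
  code <- lab[cbind(pmin(pmax(px, 1), nrow(lab)),
                    pmin(pmax(py, 1), ncol(lab)))]
  if (any(code == 0)) {
    abort_glut4("spot centroid outside the fibre region",
                "glut4_assignment_error")
  }
  spotset$spots$layer_index <- code - 1L  # 0 = PM, 1..n, n+1 = core
  spotset
}

#' Export a spot set as a tidy data.frame / CSV
#' @param spotset a `spot_set`.
#' @param path optional CSV path.
#' @return data.frame with image_id, spot_id and spot columns.
#' @export
spot_table <- function(spotset, path = NULL) {
  df <- spotset$spots
  out <- cbind(data.frame(image_id = spotset$fibre_id,
                          spot_id = seq_len(nrow(df))), df)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
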