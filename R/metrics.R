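# Per-fibre and per-layer quantities: whole-fibre raw intensity, spot counts
# / areas / mean sizes per class, per-layer intensity and large-spot density,
# and normalisation to a reference group.

#' Mean raw GLUT4 intensity over the intracellular mask
#'
#' Computed on the raw channel only; the filtered detection channel (class
#' `glut4_filtered`) is rejected so preprocessing can never leak into
#' intensity quantitation.
#'
#' @param glut4_raw raw GLUT4 channel, numeric matrix.
#' @param roi a `fibre_roi`.
#' @return arithmetic mean intensity, a.u.
#' @export
fibre_mean_intensity <- function(glut4_raw, roi) {
  if (inherits(glut4_raw, "glut4_filtered")) {
    abort_glut4("intensity metrics must use the raw channel, not the filtered one",
                "glut4_invalid_parameter")
  }
  stopifnot(inherits(roi, "fibre_roi"))
  if (!any(roi$intracellular_mask)) {
    abort_glut4("empty intracellular mask", "glut4_degenerate_fibre")
  }
  mean(glut4_raw[roi$intracellular_mask])
}

#' Per-fibre spot metrics
#'
#' Per size class: count, density (count per square micrometre of fibre
#' area), total spot area, and mean spot size computed as total spot area
#' divided by spot count (`NA`, not zero, when the class is empty). Spots in
#' the PM band (layer 0) are excluded: these are intracellular metrics.
#'
#' @param spotset a `spot_set` with layer assignments (unassigned spot sets
#'   are used whole).
#' @param fibre_area_um2 intracellular fibre area, square micrometres (> 0).
#' @return one-row data.frame: large_count, small_count, large_density,
#'   small_density, large_total_area, small_total_area, mean_large_size,
#'   mean_small_size.
#' @export
fibre_spot_metrics <- function(spotset, fibre_area_um2) {
  if (!is.finite(fibre_area_um2) || fibre_area_um2 <= 0) {
    abort_glut4("fibre area must be > 0", "glut4_degenerate_fibre")
  }
  df <- spotset$spots
  if (nrow(df) > 0 && !all(is.na(df$layer_index))) {
    df <- df[df$layer_index >= 1L, , drop = FALSE]
  }
  one <- function(cl) {
    sel <- df$class == cl
    count <- sum(sel)
    total <- sum(df$area_um2[sel])
    c(count = count, density = count / fibre_area_um2, total_area = total,
      mean_size = if (count > 0) total / count else NA_real_)
  }
  l <- one("large"); s <- one("small")
  data.frame(
    large_count = l[["count"]], small_count = s[["count"]],
    large_density = l[["density"]], small_density = s[["density"]],
    large_total_area = l[["total_area"]], small_total_area = s[["total_area"]],
    mean_large_size = l[["mean_size"]], mean_small_size = s[["mean_size"]],
    fibre_area_um2 = fibre_area_um2
  )
}

#' Per-layer metrics: mean raw intensity and large-spot density
#'
#' One row per emitted layer (0 = PM band, 1..n, n+1 = core): mean raw GLUT4
#' intensity over the layer mask (`NA` if empty), the count of large spots
#' assigned to the layer, the layer area and the count per area.
#'
#' @param glut4_raw raw GLUT4 channel.
#' @param spotset a `spot_set` with layer assignments.
#' @param layers a `layer_set`.
#' @return data.frame: layer_index, mean_intensity, large_count,
#'   layer_area_um2, large_per_area, complete.
#' @export
layer_metrics <- function(glut4_raw, spotset, layers) {
  if (inherits(glut4_raw, "glut4_filtered")) {
    abort_glut4("intensity metrics must use the raw channel, not the filtered one",
                "glut4_invalid_parameter")
  }
  stopifnot(inherits(layers, "layer_set"))
  if (nrow(spotset$spots) > 0 && anyNA(spotset$spots$layer_index)) {
    abort_glut4("spots lack layer assignments; run assign_layers() first",
                "glut4_assignment_error")
  }
  masks <- c(list(layers$pm_layer), layers$intracellular_layers,
             list(layers$core_mask))
  idx <- c(0L, seq_len(layers$n_layers), layers$n_layers + 1L)
  complete <- c(TRUE, layers$complete_flags, NA)
  rows <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    n <- sum(m)
    large_n <- sum(spotset$spots$layer_index == idx[i] &
                     spotset$spots$class == "large")
    area <- n * layers$pixel_size^2
    data.frame(
      layer_index = idx[i],
      mean_intensity = if (n > 0) mean(glut4_raw[m]) else NA_real_,
      large_count = large_n,
      layer_area_um2 = area,
      large_per_area = if (area > 0) large_n / area else NA_real_,
      complete = complete[i]
    )
  })
  do.call(rbind, rows)
}

#' Normalise a metric column to a reference group
#'
#' Divides `value_col` by the mean of the rows selected by `reference`;
#' the reference group therefore normalises itself to mean 1 exactly. The
#' study convention is pre-training type I fibres for whole-fibre metrics
#' and the pre-training PM layer for layered metrics.
#'
#' @param table data.frame.
#' @param value_col name of the value column.
#' @param reference logical vector (or expression result) selecting the
#'   reference rows.
#' @param percent multiply by 100.
#' @return the table with an added `<value_col>_rel` column.
#' @export
normalize_to_reference <- function(table, value_col, reference,
                                   percent = FALSE) {
  if (!value_col %in% names(table)) {
    abort_glut4(paste0("no column ", value_col), "glut4_invalid_parameter")
  }
  ref <- table[[value_col]][reference]
  ref <- ref[is.finite(ref)]
  if (length(ref) == 0) {
    abort_glut4("empty reference group", "glut4_invalid_parameter")
  }
  scale <- if (percent) 100 else 1
  table[[paste0(value_col, "_rel")]] <- table[[value_col]] / mean(ref) * scale
  table
}
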