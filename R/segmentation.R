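# Plasma-membrane segmentation: snake (active contour) on the dystrophin
# channel, PM-band / intracellular mask construction, and fibre typing from
# the MHCI channel.

#' Initial contour from the dystrophin channel
#'
#' Otsu-thresholds the dystrophin image, keeps the largest connected object,
#' fills it, and returns its boundary dilated outward by 3 px, resampled to
#' uniform arc-length spacing. This starting polygon lies just outside the
#' dystrophin ring so the snake contracts onto the ridge.
#'
#' @param dystrophin numeric matrix `[x, y]`.
#' @param n_vertices vertices of the returned polygon.
#' @param min_object_area_px smallest acceptable foreground object.
#' @return a `fibre_contour`: list with `vertices` (n x 2) and a
#'   `convergence_report` (empty at initialisation).
#' @export
initial_contour <- function(dystrophin, n_vertices = 120L,
                            min_object_area_px = 200L) {
  rng <- range(dystrophin)
  if (diff(rng) <= 0) {
    abort_glut4("dystrophin channel is constant; no object to segment",
                "glut4_segmentation_failure")
  }
  norm <- (dystrophin - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm))
  bin <- norm > thr
  lab <- EBImage::bwlabel(matrix(as.numeric(bin), nrow(bin), ncol(bin)))
  if (max(lab) == 0) {
    abort_glut4("no foreground object in dystrophin channel",
                "glut4_segmentation_failure")
  }
  sizes <- tabulate(lab[lab > 0])
  largest <- which.max(sizes)
  if (sizes[largest] < min_object_area_px) {
    abort_glut4("largest dystrophin object below minimum area",
                "glut4_segmentation_failure")
  }
  obj <- lab == largest
  filled <- EBImage::fillHull(matrix(as.numeric(obj), nrow(obj), ncol(obj)))
  dil <- EBImage::dilate(filled, EBImage::makeBrush(7L, "disc"))
  oc <- EBImage::ocontour(EBImage::bwlabel(dil))
  v <- oc[[which.max(vapply(oc, nrow, integer(1)))]] + 1  # ocontour is 0-based
  v <- resample_contour(v, n_vertices)
  new_fibre_contour(v)
}

new_fibre_contour <- function(vertices, iterations = 0L, final_delta = NA_real_,
                              converged = NA) {
  if (nrow(vertices) < 32L) {
    abort_glut4("fibre contour needs >= 32 vertices", "glut4_segmentation_failure")
  }
  if (polygon_area(vertices) <= 0) {
    abort_glut4("fibre contour encloses no area", "glut4_segmentation_failure")
  }
  structure(list(
    vertices = vertices,
    convergence_report = list(iterations = iterations,
                              final_delta = final_delta,
                              converged = converged)
  ), class = "fibre_contour")
}

#' @export
print.fibre_contour <- function(x, ...) {
  cr <- x$convergence_report
  cat(sprintf("<fibre_contour> %d vertices, area %.0f px^2, iter %d, delta %.4g\n",
              nrow(x$vertices), polygon_area(x$vertices),
              cr$iterations, cr$final_delta))
  invisible(x)
}

# external attraction potential: the snake climbs this surface.
# line term rewards bright ridge intensity (the dystrophin band midline);
# edge term rewards gradient magnitude (classical edge functional).
snake_potential <- function(img, sigma, line_weight, edge_weight) {
  s <- gauss_blur(img, sigma)
  rs <- range(s)
  s <- if (diff(rs) > 0) (s - rs[1]) / diff(rs) else s * 0
  p <- line_weight * s
  if (edge_weight != 0) {
    gr <- grad_xy(s)
    e <- gr$gx^2 + gr$gy^2
    re <- range(e)
    if (diff(re) > 0) e <- (e - re[1]) / diff(re)
    p <- p + edge_weight * e
  }
  p
}

#' Evolve an active contour (snake) onto the dystrophin ridge
#'
#' Minimises the Kass internal energy `integral (alpha |v'|^2 +
#' beta |v''|^2)/2 ds` plus an external energy built from the smoothed
#' dystrophin image. The default external energy is the bright-line (ridge)
#' functional `-(G_sigma * I)`, which equilibrates on the midline of the
#' dystrophin band; the classical edge functional `-|grad(G_sigma * I)|^2`
#' can be blended in via `snake_edge_weight`. The contour is updated
#' semi-implicitly (internal forces implicit, external explicit) and
#' resampled to uniform arc length every iteration; evolution stops when the
#' maximum vertex displacement per iteration falls below `snake_tol_px` or
#' the iteration cap is reached (warning, best contour returned flagged).
#'
#' @param dystrophin numeric matrix `[x, y]`.
#' @param init a `fibre_contour` from [initial_contour()].
#' @param cfg a [pipeline_config()] (snake parameters are read from it).
#' @return a `fibre_contour` with a filled `convergence_report`
#'   (`iterations`, `final_delta`, `converged`, `energy` trace).
#' @export
evolve_snake <- function(dystrophin, init, cfg = pipeline_config()) {
  stopifnot(inherits(init, "fibre_contour"))
  n <- nrow(init$vertices)
  p <- snake_potential(dystrophin, cfg$snake_sigma_px,
                       cfg$snake_line_weight, cfg$snake_edge_weight)
  gr <- grad_xy(p)
  tau <- cfg$snake_step
  a <- internal_matrix(n, cfg$snake_alpha, cfg$snake_beta)
  minv <- solve(diag(n) + tau * a)
  v <- init$vertices
  energy <- numeric(0)
  delta <- Inf
  iter <- 0L
  while (iter < cfg$snake_max_iter) {
    iter <- iter + 1L
    fx <- bilinear(gr$gx, v[, 1], v[, 2])
    fy <- bilinear(gr$gy, v[, 1], v[, 2])
    vn <- cbind(minv %*% (v[, 1] + tau * cfg$snake_kappa * fx),
                minv %*% (v[, 2] + tau * cfg$snake_kappa * fy))
    vn <- resample_contour(vn, n)
    delta <- max(sqrt(rowSums((vn - v)^2)))
    v <- vn
    energy <- c(energy, snake_energy(v, a, p, cfg$snake_kappa))
    if (delta < cfg$snake_tol_px) break
  }
  converged <- delta < cfg$snake_tol_px
  if (!converged) {
    warn_glut4(sprintf("snake did not converge in %d iterations (delta %.3g px)",
                       iter, delta), "glut4_snake_nonconvergence")
  }
  out <- new_fibre_contour(v, iterations = iter, final_delta = delta,
                           converged = converged)
  out$convergence_report$energy <- energy
  out
}

# circulant internal-energy stiffness matrix: alpha * L + beta * L^2 with L
# the periodic second-difference operator
internal_matrix <- function(n, alpha, beta) {
  l <- matrix(0, n, n)
  idx <- seq_len(n)
  l[cbind(idx, idx)] <- 2
  l[cbind(idx, idx %% n + 1L)] <- -1
  l[cbind(idx %% n + 1L, idx)] <- -1
  alpha * l + beta * (l %*% l)
}

snake_energy <- function(v, a, p, kappa) {
  internal <- 0.5 * (sum(v[, 1] * (a %*% v[, 1])) + sum(v[, 2] * (a %*% v[, 2])))
  external <- -kappa * sum(bilinear(p, v[, 1], v[, 2]))
  internal + external
}

#' Build PM-band and intracellular masks from a converged contour
#'
#' The PM band contains every pixel whose centre lies within
#' `band_halfwidth_px` of the contour polyline (total thickness
#' `2 * band_halfwidth_px`, i.e. 5 px at the default halfwidth of 2.5); the
#' intracellular mask contains the interior pixels beyond the band. Band,
#' intracellular mask and exterior partition the image.
#'
#' @param contour a `fibre_contour`.
#' @param dim image dimensions (nx, ny).
#' @param pixel_size micrometres per pixel.
#' @param band_halfwidth_px band halfwidth about the midline, pixels.
#' @param fibre_type optional `"I"`/`"II"` (set by [classify_fibre_type()]).
#' @return a `fibre_roi`: list with `contour`, `pm_band_mask`,
#'   `intracellular_mask`, `fibre_type`, `pixel_size`.
#' @export
make_masks <- function(contour, dim, pixel_size, band_halfwidth_px = 2.5,
                       fibre_type = NA_character_) {
  stopifnot(inherits(contour, "fibre_contour"))
  m <- contour_band_masks(contour$vertices, dim, band_halfwidth_px)
  if (!any(m$interior)) {
    abort_glut4("PM band covers the whole fibre (degenerate fibre)",
                "glut4_degenerate_fibre")
  }
  structure(list(
    contour = contour, pm_band_mask = m$band,
    intracellular_mask = m$interior, fibre_type = fibre_type,
    pixel_size = pixel_size
  ), class = "fibre_roi")
}

#' Segment one fibre: initialisation + snake + masks
#'
#' Convenience wrapper running [initial_contour()], [evolve_snake()] and
#' [make_masks()] on a calibrated image.
#'
#' @param img a [calibrated_image()].
#' @param cfg a [pipeline_config()].
#' @return a `fibre_roi`.
#' @export
segment_fibre <- function(img, cfg = pipeline_config()) {
  dys <- img$channels$dystrophin
  init <- initial_contour(dys, n_vertices = cfg$snake_n_vertices,
                          min_object_area_px = cfg$min_object_area_px)
  sc <- evolve_snake(dys, init, cfg)
  make_masks(sc, dim(dys), img$pixel_size,
             band_halfwidth_px = cfg$band_halfwidth_px)
}

#' Mean MHCI intensity inside the intracellular mask
#' @param mhc1 numeric matrix.
#' @param roi a `fibre_roi`.
#' @return scalar mean intensity, a.u.
#' @export
mhc1_mean <- function(mhc1, roi) {
  stopifnot(inherits(roi, "fibre_roi"))
  mean(mhc1[roi$intracellular_mask])
}

#' Otsu threshold of a numeric vector (exhaustive search)
#'
#' Maximises between-class variance over midpoints of the sorted values;
#' used for batch fibre typing where the per-fibre MHCI means are assumed
#' bimodal.
#' @param x numeric vector, length >= 2.
#' @return scalar threshold.
#' @export
otsu_vector <- function(x) {
  if (length(x) < 2L) {
    abort_glut4("need >= 2 values for a batch threshold",
                "glut4_insufficient_data")
  }
  xs <- sort(unique(x))
  if (length(xs) == 1L) return(xs)
  cand <- (xs[-1] + xs[-length(xs)]) / 2
  bcv <- vapply(cand, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    length(lo) * length(hi) * (mean(hi) - mean(lo))^2
  }, numeric(1))
  cand[which.max(bcv)]
}

#' Classify fibre types from per-fibre MHCI means
#'
#' Default strategy thresholds the batch of per-fibre mean MHCI intensities
#' with an Otsu split (bimodal assumption): means above the threshold are
#' type I (MHCI-positive), below are type II. A fixed threshold may be
#' supplied instead for single fibres.
#'
#' @param means numeric vector of per-fibre mean MHCI intensities.
#' @param strategy `"batch_otsu"` or `"fixed"`.
#' @param threshold fixed threshold (required when `strategy = "fixed"`).
#' @return character vector of `"I"` / `"II"`.
#' @export
classify_fibre_type <- function(means, strategy = c("batch_otsu", "fixed"),
                                threshold = NULL) {
  strategy <- match.arg(strategy)
  thr <- if (strategy == "fixed") {
    if (is.null(threshold)) {
      abort_glut4("fixed strategy requires a threshold", "glut4_invalid_parameter")
    }
    threshold
  } else {
    otsu_vector(means)
  }
  ifelse(means > thr, "I", "II")
}
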