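# Synthetic single-fibre confocal field generator with machine-readable
# ground truth. Emulates the study's imaging design: one dominant fibre per
# image bounded by a bright dystrophin ring, GLUT4 as large (>1 um) and small
# (<1 um) clusters enriched at the periphery and around nuclei over a diffuse
# interior background, and a bimodal MHCI channel separating type I from
# type II fibres.

#' Deterministic 31-bit seed derived from a master seed and a key
#'
#' Polynomial string hash mixed with the master seed; used to give every
#' generated image its own reproducible RNG stream.
#' @keywords internal
derive_seed <- function(master_seed, ...) {
  key <- paste(c(...), collapse = "|")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + (master_seed %% 2147483647) * 48271) %% 2147483647)
}

#' Generate the geometry of a synthetic muscle fibre
#'
#' Builds the ground-truth skeleton: a closed, star-shaped plasma-membrane
#' midline contour whose radius is `radius_um` modulated by a smooth random
#' perturbation of relative amplitude at most `irregularity`, a rasterised
#' interior mask, and 3-8 peripheral nuclei.
#'
#' @param radius_um mean fibre radius, micrometres (>= 5).
#' @param irregularity relative radial perturbation in `[0, 1)`.
#' @param pixel_size micrometres per pixel (> 0).
#' @param seed integer RNG seed; identical seed + parameters give
#'   bit-identical output.
#' @param fibre_type `"I"` or `"II"`.
#' @param margin_um clear margin between fibre and image border.
#' @return object of class `ground_truth` with elements `contour` (n x 2
#'   pixel coordinates of the PM midline), `interior_mask`, `centre`, `dim`,
#'   `nuclei`, `fibre_type`, `pixel_size`, `seed`; `spots` is empty until
#'   [plant_spots()] is called.
#' @export
generate_fibre_geometry <- function(radius_um, irregularity = 0.15,
                                    pixel_size = 0.2, seed = 1L,
                                    fibre_type = c("I", "II"),
                                    margin_um = 6) {
  stopifnot_scalar_number(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar_number(radius_um, "radius_um", positive = TRUE)
  if (radius_um < 5) {
    abort_glut4("radius_um must be >= 5 um", "glut4_invalid_parameter")
  }
  fibre_type <- match.arg(fibre_type)
  radius_px <- radius_um / pixel_size
  margin_px <- margin_um / pixel_size
  half <- ceiling(radius_px * (1 + irregularity) + margin_px)
  n <- as.integer(2 * half + 1)
  centre <- c((n + 1) / 2, (n + 1) / 2)
  withr::with_seed(as.integer(seed), {
    contour <- radial_contour(centre, radius_px, irregularity,
                              n_vertices = 720L)
    n_nuc <- sample(3:8, 1)
    ang <- stats::runif(n_nuc, 0, 2 * pi)
    depth_um <- stats::runif(n_nuc, 1.5, 4)      # subsarcolemmal position
    nuc_r_um <- pmax(1.5, stats::rnorm(n_nuc, 2.5, 0.3))
    r_theta <- radial_at_angle(contour, centre, ang)
    nuclei <- data.frame(
      x = centre[1] + (r_theta - depth_um / pixel_size) * cos(ang),
      y = centre[2] + (r_theta - depth_um / pixel_size) * sin(ang),
      radius_um = nuc_r_um
    )
  })
  structure(list(
    contour = contour, centre = centre, dim = c(n, n),
    interior_mask = fill_contour(contour, c(n, n)),
    nuclei = nuclei, fibre_type = fibre_type,
    spots = empty_spot_truth(), background_level = 1500,
    peripheral_gradient = 0.8, peripheral_scale_um = 1.0,
    pixel_size = pixel_size, radius_um = radius_um, seed = as.integer(seed)
  ), class = "ground_truth")
}

empty_spot_truth <- function() {
  data.frame(x = numeric(0), y = numeric(0), diameter_um = numeric(0),
             class = character(0), radial_depth_um = numeric(0),
             amplitude = numeric(0), stringsAsFactors = FALSE)
}

# radius of the star-shaped contour at given polar angles (linear interp)
radial_at_angle <- function(contour, centre, ang) {
  th <- atan2(contour[, 2] - centre[2], contour[, 1] - centre[1]) %% (2 * pi)
  r <- sqrt((contour[, 1] - centre[1])^2 + (contour[, 2] - centre[2])^2)
  o <- order(th)
  th <- th[o]; r <- r[o]
  stats::approx(c(th - 2 * pi, th, th + 2 * pi), rep(r, 3),
                xout = ang %% (2 * pi), ties = "ordered")$y
}

#' Plant ground-truth GLUT4 spots in a fibre
#'
#' Adds exactly `n_large` spots with diameter > 1 um and `n_small` with
#' diameter < 1 um (diameters within 0.05 um of the class boundary are
#' resampled to avoid ground-truth ambiguity). A fraction of spots is placed
#' peripherally (radial depth from the PM midline <= 1 um), a fraction within
#' 2 um of a nuclear boundary, the remainder uniformly in the interior.
#' Overlapping placements (centre distance below the sum of radii) are
#' rejected and resampled.
#'
#' @param truth a `ground_truth` from [generate_fibre_geometry()].
#' @param n_large,n_small spot counts per class.
#' @param large_diam,small_diam `(mean, sd)` of the sampled diameters, um.
#' @param peripheral_fraction,perinuclear_fraction placement fractions in
#'   `[0, 1]`, summing to at most 1.
#' @param seed integer RNG seed.
#' @param max_tries per-spot rejection-sampling limit.
#' @return the `ground_truth` with its `spots` data.frame populated
#'   (columns x, y, diameter_um, class, radial_depth_um, amplitude).
#' @export
plant_spots <- function(truth, n_large, n_small,
                        large_diam = c(1.6, 0.3), small_diam = c(0.65, 0.12),
                        peripheral_fraction = 0.4, perinuclear_fraction = 0.2,
                        seed = truth$seed + 1L, max_tries = 400L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (peripheral_fraction < 0 || perinuclear_fraction < 0 ||
      peripheral_fraction > 1 || perinuclear_fraction > 1 ||
      peripheral_fraction + perinuclear_fraction > 1) {
    abort_glut4("placement fractions must lie in [0,1] and sum to <= 1",
                "glut4_invalid_parameter")
  }
  n_large <- as.integer(n_large); n_small <- as.integer(n_small)
  if (n_large < 0 || n_small < 0) {
    abort_glut4("spot counts must be >= 0", "glut4_invalid_parameter")
  }
  ps <- truth$pixel_size
  n_tot <- n_large + n_small
  if (n_tot == 0) { truth$spots <- empty_spot_truth(); return(truth) }

  sample_diam <- function(mean, sd, lower, upper) {
    for (i in seq_len(200)) {
      d <- stats::rnorm(1, mean, sd)
      # resample near the 1 um boundary and outside plausible bounds
      if (d >= lower && d <= upper && abs(d - 1) > 0.05) return(d)
    }
    abort_glut4("could not sample a spot diameter in bounds",
                "glut4_invalid_parameter")
  }
  interior_idx <- which(truth$interior_mask, arr.ind = TRUE)
  # decimated contour for distance queries (chord error << pixel scale)
  vq <- if (nrow(truth$contour) > 256L) {
    resample_contour(truth$contour, 256L)
  } else truth$contour

  withr::with_seed(as.integer(seed), {
    classes <- c(rep("large", n_large), rep("small", n_small))
    diam <- vapply(classes, function(cl) {
      if (cl == "large") sample_diam(large_diam[1], large_diam[2], 1.05, 5)
      else sample_diam(small_diam[1], small_diam[2], 0.3, 0.95)
    }, numeric(1))
    # deterministic placement category counts, spread across both classes
    n_peri <- round(peripheral_fraction * n_tot)
    n_nuc <- round(perinuclear_fraction * n_tot)
    cat_pool <- c(rep("peripheral", n_peri), rep("perinuclear", n_nuc),
                  rep("interior", n_tot - n_peri - n_nuc))
    category <- sample(cat_pool, n_tot)

    xs <- numeric(n_tot); ys <- numeric(n_tot); depth <- numeric(n_tot)
    for (i in seq_len(n_tot)) {
      placed <- FALSE
      r_px <- diam[i] / 2 / ps
      for (try in seq_len(max_tries)) {
        if (category[i] == "peripheral") {
          ang <- stats::runif(1, 0, 2 * pi)
          d_um <- stats::runif(1, 0.15, 1.0)
          rr <- radial_at_angle(truth$contour, truth$centre, ang) - d_um / ps
          cand <- truth$centre + rr * c(cos(ang), sin(ang))
        } else if (category[i] == "perinuclear") {
          k <- sample(nrow(truth$nuclei), 1)
          ang <- stats::runif(1, 0, 2 * pi)
          off <- (truth$nuclei$radius_um[k] + stats::runif(1, 0.1, 2)) / ps
          cand <- c(truth$nuclei$x[k], truth$nuclei$y[k]) +
            off * c(cos(ang), sin(ang))
        } else {
          j <- sample(nrow(interior_idx), 1)
          cand <- interior_idx[j, ] + stats::runif(2, -0.5, 0.5)
        }
        px <- round(cand)
        if (px[1] < 1 || px[2] < 1 || px[1] > truth$dim[1] ||
            px[2] > truth$dim[2] || !truth$interior_mask[px[1], px[2]]) next
        d_true <- dist_to_polyline(matrix(cand, 1), vq) * ps
        if (category[i] == "peripheral" && d_true > 1.0) next
        if (i > 1) {
          dd <- sqrt((xs[1:(i - 1)] - cand[1])^2 + (ys[1:(i - 1)] - cand[2])^2)
          if (any(dd < r_px + diam[1:(i - 1)] / 2 / ps)) next
        }
        xs[i] <- cand[1]; ys[i] <- cand[2]; depth[i] <- d_true
        placed <- TRUE
        break
      }
      if (!placed) {
        abort_glut4(sprintf("could not place spot %d of %d without overlap",
                            i, n_tot), "glut4_placement_error")
      }
    }
    amplitude <- pmax(4000, stats::rnorm(n_tot, 8000, 800))
    truth$spots <- data.frame(
      x = xs, y = ys, diameter_um = diam, class = classes,
      radial_depth_um = depth, amplitude = amplitude,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  truth
}

#' Render a ground truth into a calibrated multi-channel image
#'
#' GLUT4 = uniform spot disks + diffuse interior background with a
#' peripheral-to-core exponential gradient; dystrophin = bright band centred
#' on the PM midline contour; MHCI = high interior mean for type I fibres,
#' low for type II; DAPI = nuclear disks. All channels are convolved with a
#' Gaussian point-spread function and optionally corrupted by noise.
#'
#' @param truth a `ground_truth`.
#' @param psf_sigma PSF standard deviation, micrometres (>= 0; 0 disables).
#' @param noise list with `gaussian_sd` (a.u.) and `poisson` (logical).
#' @param gains named list overriding channel rendering constants
#'   (`glut4_base`, `glut4_gain`, `dystrophin_gain`, `band_halfwidth_px`,
#'   `mhc1_type1`, `mhc1_type2`, `dapi_gain`).
#' @param seed RNG seed for the noise draw.
#' @return a [calibrated_image()] with channels glut4, dystrophin, mhc1, dapi.
#' @export
render_image <- function(truth, psf_sigma = 0.2,
                         noise = list(gaussian_sd = 0, poisson = FALSE),
                         gains = list(), seed = truth$seed + 2L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (psf_sigma < 0) abort_glut4("psf_sigma must be >= 0",
                                 "glut4_invalid_parameter")
  g <- utils::modifyList(list(
    glut4_base = 200, glut4_gain = 1, dystrophin_gain = 9000,
    band_halfwidth_px = 2.5, mhc1_type1 = 9000, mhc1_type2 = 1200,
    dapi_gain = 8000, base_offset = 150
  ), gains)
  ps <- truth$pixel_size
  d <- truth$dim
  fillm <- truth$interior_mask

  # diffuse interior background with peripheral enrichment
  glut4 <- matrix(g$glut4_base, d[1], d[2])
  if (any(fillm)) {
    din <- as.matrix(EBImage::distmap(matrix(as.numeric(fillm), d[1], d[2])))
    depth_um <- din * ps
    bg <- truth$background_level *
      (1 + truth$peripheral_gradient * exp(-depth_um / truth$peripheral_scale_um))
    glut4[fillm] <- glut4[fillm] + g$glut4_gain * bg[fillm]
  }
  # spots as uniform disks at their ground-truth diameters
  if (nrow(truth$spots) > 0) {
    for (i in seq_len(nrow(truth$spots))) {
      glut4 <- add_disk(glut4, truth$spots$x[i], truth$spots$y[i],
                        truth$spots$diameter_um[i] / 2 / ps,
                        g$glut4_gain * truth$spots$amplitude[i])
    }
  }
  masks <- contour_band_masks(truth$contour, d, g$band_halfwidth_px)
  dystrophin <- matrix(g$base_offset, d[1], d[2])
  dystrophin[masks$band] <- dystrophin[masks$band] + g$dystrophin_gain
  mhc1 <- matrix(g$base_offset, d[1], d[2])
  mhc1[fillm] <- mhc1[fillm] +
    if (truth$fibre_type == "I") g$mhc1_type1 else g$mhc1_type2
  dapi <- matrix(g$base_offset, d[1], d[2])
  for (i in seq_len(nrow(truth$nuclei))) {
    dapi <- add_disk(dapi, truth$nuclei$x[i], truth$nuclei$y[i],
                     truth$nuclei$radius_um[i] / ps, g$dapi_gain)
  }
  ch <- list(glut4 = glut4, dystrophin = dystrophin, mhc1 = mhc1, dapi = dapi)
  if (psf_sigma > 0) {
    ch <- lapply(ch, gauss_blur, sigma = psf_sigma / ps)
  }
  gn <- noise$gaussian_sd %||% 0
  if (isTRUE(noise$poisson) || gn > 0) {
    ch <- withr::with_seed(as.integer(seed), {
      lapply(ch, function(m) {
        if (isTRUE(noise$poisson)) m <- matrix(stats::rpois(length(m), m), d[1], d[2])
        if (gn > 0) m <- m + stats::rnorm(length(m), 0, gn)
        m
      })
    })
  }
  ch <- lapply(ch, function(m) pmin(pmax(m, 0), INTENSITY_MAX))
  calibrated_image(ch, ps, image_id = sprintf("synth_seed%d", truth$seed))
}

# additive uniform disk rasterised over pixel centres
add_disk <- function(m, cx, cy, r_px, value) {
  x0 <- max(1, floor(cx - r_px - 1)); x1 <- min(nrow(m), ceiling(cx + r_px + 1))
  y0 <- max(1, floor(cy - r_px - 1)); y1 <- min(ncol(m), ceiling(cy + r_px + 1))
  if (x1 < x0 || y1 < y0) return(m)
  xs <- x0:x1; ys <- y0:y1
  dd <- outer((xs - cx)^2, (ys - cy)^2, "+")
  sub <- m[xs, ys, drop = FALSE]
  sub[dd <= r_px^2] <- sub[dd <= r_px^2] + value
  m[xs, ys] <- sub
  m
}
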