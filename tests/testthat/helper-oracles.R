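# Independent oracles: deliberately different algorithms from the package
# implementations they check.

# winding-number point-in-polygon test (package uses even-odd scanline fill)
pip_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  wn <- numeric(length(px))
  for (e in seq_len(n)) {
    j <- if (e == n) 1L else e + 1L
    x1 <- poly[e, 1]; y1 <- poly[e, 2]
    x2 <- poly[j, 1]; y2 <- poly[j, 2]
    side <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    up <- y1 <= py & y2 > py & side > 0
    down <- y1 > py & y2 <= py & side < 0
    wn <- wn + up - down
  }
  wn != 0
}

# O(N*M) distance map: per foreground pixel, min distance over all background
# pixel centres (package uses EBImage's distance transform)
brute_distance_map <- function(mask) {
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(fg))) {
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((fg[i, 1] - bg[, 1])^2 + (fg[i, 2] - bg[, 2])^2))
  }
  out
}

# min distance to a closed polyline via dense resampling of every edge
# (package computes exact point-to-segment projections)
polyline_dist_oracle <- function(p, poly, samples_per_edge = 200) {
  pts <- NULL
  n <- nrow(poly)
  for (e in seq_len(n)) {
    j <- if (e == n) 1L else e + 1L
    t <- seq(0, 1, length.out = samples_per_edge)
    pts <- rbind(pts, cbind(poly[e, 1] + t * (poly[j, 1] - poly[e, 1]),
                            poly[e, 2] + t * (poly[j, 2] - poly[e, 2])))
  }
  apply(p, 1, function(q) sqrt(min((pts[, 1] - q[1])^2 + (pts[, 2] - q[2])^2)))
}

# balanced cell-means SS decomposition for the mixed design
# (package route goes through stats::aov + Error strata)
oracle_mixed_anova <- function(df) {
  y <- df$value; g <- mean(y)
  a <- length(unique(df$mode)); tt <- length(unique(df$training))
  n <- length(unique(df$subject)) / a
  m_mode <- tapply(y, df$mode, mean)
  m_train <- tapply(y, df$training, mean)
  m_subj <- tapply(y, df$subject, mean)
  ss_mode <- tt * n * sum((m_mode - g)^2)
  ss_subj_tot <- tt * sum((m_subj - g)^2)
  ss_train <- a * n * sum((m_train - g)^2)
  cells <- tapply(y, list(df$mode, df$training), mean)
  ss_int <- n * sum((sweep(sweep(cells, 1, m_mode), 2, m_train) + g)^2)
  ss_total <- sum((y - g)^2)
  list(mode = ss_mode, subj_within = ss_subj_tot - ss_mode,
       training = ss_train, interaction = ss_int,
       resid = ss_total - ss_subj_tot - ss_train - ss_int,
       total = ss_total)
}

# balanced two-within decomposition with per-effect subject interactions
oracle_two_within <- function(df) {
  y <- df$value; g <- mean(y)
  s <- factor(df$subject); tr <- factor(df$training); l <- factor(df$layer)
  ns <- nlevels(s); nt <- nlevels(tr); nl <- nlevels(l)
  m_s <- tapply(y, s, mean); m_t <- tapply(y, tr, mean); m_l <- tapply(y, l, mean)
  ss_s <- nt * nl * sum((m_s - g)^2)
  ss_t <- ns * nl * sum((m_t - g)^2)
  ss_l <- ns * nt * sum((m_l - g)^2)
  c_tl <- tapply(y, list(tr, l), mean)
  ss_tl <- ns * sum((sweep(sweep(c_tl, 1, m_t), 2, m_l) + g)^2)
  c_ts <- tapply(y, list(tr, s), mean)
  ss_ts <- nl * sum((sweep(sweep(c_ts, 1, m_t), 2, m_s) + g)^2)
  c_ls <- tapply(y, list(l, s), mean)
  ss_ls <- nt * sum((sweep(sweep(c_ls, 1, m_l), 2, m_s) + g)^2)
  ss_total <- sum((y - g)^2)
  ss_tls <- ss_total - ss_s - ss_t - ss_l - ss_tl - ss_ts - ss_ls
  list(subject = ss_s, training = ss_t, layer = ss_l, interaction = ss_tl,
       err_training = ss_ts, err_layer = ss_ls, err_interaction = ss_tls,
       total = ss_total)
}

# ---------------------------------------------------------------------------
# shared fixtures (built once per test run)

.fixtures <- new.env(parent = emptyenv())

# small noiseless rendered fibre with planted spots, segmented and layered
small_fibre_fixture <- function() {
  if (is.null(.fixtures$small)) {
    gt <- generate_fibre_geometry(20, irregularity = 0.12, pixel_size = 0.2,
                                  seed = 21)
    gt <- plant_spots(gt, 8, 25, seed = 22)
    img <- render_image(gt, psf_sigma = 0.2, noise = list(gaussian_sd = 0))
    cfg <- pipeline_config(n_layers = 12)
    roi <- segment_fibre(img, cfg)
    layers <- build_layers(roi, n_layers = 12)
    .fixtures$small <- list(gt = gt, img = img, cfg = cfg, roi = roi,
                            layers = layers)
  }
  .fixtures$small
}

# noiseless perfect ring at the scale of the headline segmentation checks
ring_fixture <- function() {
  if (is.null(.fixtures$ring)) {
    gt <- generate_fibre_geometry(30, irregularity = 0, pixel_size = 0.2,
                                  seed = 1)
    img <- render_image(gt, psf_sigma = 0.2, noise = list(gaussian_sd = 0))
    .fixtures$ring <- list(gt = gt, img = img)
  }
  .fixtures$ring
}

# subject-level table generators for the statistics simulations; the planted
# training effect delta is expressed as Cohen's d_z (relative to the SD of
# the within-subject pre-post change)
sim_mixed_table <- function(n_per_mode = 8, delta = 0, sd_subject = 1) {
  n <- 2 * n_per_mode
  subj <- sprintf("s%02d", 1:n)
  mode <- rep(c("ET", "SIT"), each = n_per_mode)
  base <- stats::rnorm(n, 10, sd_subject)
  sd_eps <- 1 / sqrt(2)  # within-subject change has SD 1
  data.frame(
    subject = rep(subj, 2), mode = rep(mode, 2),
    training = rep(c("pre", "post"), each = n),
    value = c(base + stats::rnorm(n, 0, sd_eps),
              base + delta + stats::rnorm(n, 0, sd_eps))
  )
}

sim_two_within_table <- function(n_subjects = 8, n_layers = 6, delta = 0,
                                 effect_layers = integer(0), sd_subject = 1) {
  subj <- sprintf("s%02d", 1:n_subjects)
  grid <- expand.grid(subject = subj, training = c("pre", "post"),
                      layer = seq_len(n_layers) - 1L,
                      stringsAsFactors = FALSE)
  base <- stats::rnorm(n_subjects, 10, sd_subject)
  names(base) <- subj
  sd_eps <- 1 / sqrt(2)
  grid$value <- base[grid$subject] +
    ifelse(grid$training == "post" & grid$layer %in% effect_layers, delta, 0) +
    stats::rnorm(nrow(grid), 0, sd_eps)
  grid
}

# circle contour as a fibre_contour for degenerate-geometry tests
new_contour_for_test <- function(r_px, dim, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  v <- cbind((dim[1] + 1) / 2 + r_px * cos(th),
             (dim[2] + 1) / 2 + r_px * sin(th))
  glut4layers:::new_fibre_contour(v)
}
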