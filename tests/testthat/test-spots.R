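# GLUT4 preprocessing, spot detection, classification, layer assignment.

test_that("preprocessing removes flat background and boosts spot SNR", {
  cfg <- pipeline_config(pre_background_weight = 1)
  flat <- matrix(500, 64, 64)
  f <- preprocess_glut4(flat, cfg)
  expect_lt(max(f), 1e-6)  # zero up to FFT round-off
  # single spot on flat background: local contrast strictly increases
  img <- matrix(500, 96, 96)
  img <- glut4layers:::add_disk(img, 48, 48, 3, 4000)
  snr <- function(m) max(m[44:52, 44:52]) / max(mean(m[1:20, 1:20]), 1e-6)
  f2 <- preprocess_glut4(img, pipeline_config())
  expect_gt(snr(unclass(f2)), snr(img))
  # non-negativity for arbitrary input
  set.seed(4)
  noisy <- matrix(runif(64 * 64, 0, 1000), 64, 64)
  expect_true(all(preprocess_glut4(noisy, pipeline_config()) >= 0))
})

test_that("detection finds exactly the planted well-separated disks", {
  ps <- 0.2
  gt <- generate_fibre_geometry(20, irregularity = 0, pixel_size = ps, seed = 2)
  gt$spots <- data.frame(
    x = gt$centre[1] + c(-40, 0, 40), y = gt$centre[2] + c(0, -40, 40),
    diameter_um = c(1.6, 2.0, 0.8), class = c("large", "large", "small"),
    radial_depth_um = NA, amplitude = 8000
  )
  img <- render_image(gt, psf_sigma = 0.05, noise = list(gaussian_sd = 0))
  cfg <- pipeline_config()
  roi <- segment_fibre(img, cfg)
  filt <- preprocess_glut4(img$channels$glut4, cfg)
  region <- roi$pm_band_mask | roi$intracellular_mask
  ss <- detect_spots(filt, region, cfg$spot_intensity_threshold,
                     cfg$spot_min_area_px, ps)
  expect_equal(nrow(ss$spots), 3)
  expect_equal(sort(table(ss$spots$class), decreasing = TRUE),
               sort(table(c("large", "large", "small")), decreasing = TRUE))
  # centroids within a pixel of the planted centres
  ord <- order(ss$spots$x)
  planted <- gt$spots[order(gt$spots$x), ]
  expect_equal(ss$spots$x[ord], planted$x, tolerance = 1)
  expect_equal(ss$spots$y[ord], planted$y, tolerance = 1)
  # threshold above the maximum -> empty set (valid outcome)
  none <- detect_spots(filt, region, max(unclass(filt)) + 1, 4, ps)
  expect_equal(nrow(none$spots), 0)
})

test_that("two disks merged by proximity yield one spot (documented behaviour)", {
  ps <- 0.2
  gt <- generate_fibre_geometry(15, irregularity = 0, pixel_size = ps, seed = 3)
  gt$spots <- data.frame(
    x = gt$centre[1] + c(-2, 2), y = gt$centre[2],
    diameter_um = c(1.2, 1.2), class = "large",
    radial_depth_um = NA, amplitude = 8000
  )
  img <- render_image(gt, psf_sigma = 0.1, noise = list(gaussian_sd = 0))
  cfg <- pipeline_config()
  roi <- segment_fibre(img, cfg)
  filt <- preprocess_glut4(img$channels$glut4, cfg)
  ss <- detect_spots(filt, roi$pm_band_mask | roi$intracellular_mask,
                     cfg$spot_intensity_threshold, 4, ps)
  expect_equal(nrow(ss$spots), 1)
})

test_that("raising thresholds never increases the spot count", {
  fx <- small_fibre_fixture()
  filt <- preprocess_glut4(fx$img$channels$glut4, fx$cfg)
  region <- fx$roi$pm_band_mask | fx$roi$intracellular_mask
  counts_thr <- vapply(c(2000, 4000, 6000, 9000, 12000), function(thr) {
    nrow(detect_spots(filt, region, thr, 4, 0.2)$spots)
  }, numeric(1))
  expect_true(all(diff(counts_thr) <= 0))
  counts_area <- vapply(c(1, 4, 9, 16, 30), function(a) {
    nrow(detect_spots(filt, region, 4500, a, 0.2)$spots)
  }, numeric(1))
  expect_true(all(diff(counts_area) <= 0))
})

test_that("equivalent diameter follows the closed form and is monotone", {
  expect_equal(equivalent_diameter(pi / 4), 1.0)
  expect_equal(equivalent_diameter(1.0), 2 / sqrt(pi))
  a <- sort(runif(20, 0.1, 5))
  expect_true(all(diff(equivalent_diameter(a)) > 0))
  expect_error(equivalent_diameter(0), class = "glut4_invalid_spot")
})

test_that("size classification applies the 1 um rule with boundary to large", {
  expect_identical(classify_spot(1.5), "large")
  expect_identical(classify_spot(0.5), "small")
  expect_identical(classify_spot(1.0), "large")  # documented tie-break
  expect_error(classify_spot(-1), class = "glut4_invalid_spot")
  # every detected spot in exactly one class
  fx <- small_fibre_fixture()
  filt <- preprocess_glut4(fx$img$channels$glut4, fx$cfg)
  ss <- detect_spots(filt, fx$roi$intracellular_mask, 4500, 4, 0.2)
  expect_true(all(ss$spots$class %in% c("large", "small")))
})

test_that("layer assignment matches brute-force depth binning of centroids", {
  fx <- small_fibre_fixture()
  filt <- preprocess_glut4(fx$img$channels$glut4, fx$cfg)
  region <- fx$roi$pm_band_mask | fx$roi$intracellular_mask
  ss <- detect_spots(filt, region, 4500, 4, 0.2, fibre_id = "fx")
  ss <- assign_layers(ss, fx$layers)
  # oracle: depth of the centroid pixel via the brute-force distance map
  bd <- brute_distance_map(fx$roi$intracellular_mask) * 0.2
  for (i in seq_len(nrow(ss$spots))) {
    px <- round(ss$spots$x[i]); py <- round(ss$spots$y[i])
    if (fx$roi$pm_band_mask[px, py]) {
      expect_equal(ss$spots$layer_index[i], 0L)
    } else {
      k <- ceiling(bd[px, py] / fx$layers$thickness_um - 1e-9)
      expect_equal(ss$spots$layer_index[i], min(k, fx$layers$n_layers + 1L))
    }
  }
})
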