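# Ground-truth generator: geometry, spot planting, rendering, study assembly.

test_that("circular fibre geometry matches closed-form area and is deterministic", {
  gt <- generate_fibre_geometry(30, irregularity = 0, pixel_size = 0.2, seed = 1)
  r_px <- 30 / 0.2
  expect_equal(sum(gt$interior_mask), pi * r_px^2, tolerance = 0.01)
  gt2 <- generate_fibre_geometry(30, irregularity = 0, pixel_size = 0.2, seed = 1)
  expect_identical(gt$contour, gt2$contour)
  expect_identical(gt$interior_mask, gt2$interior_mask)
  expect_identical(gt$nuclei, gt2$nuclei)
})

test_that("irregular geometry stays within radial bounds and agrees with a point-in-polygon oracle", {
  gt <- generate_fibre_geometry(12, irregularity = 0.2, pixel_size = 0.25, seed = 1)
  r_px <- 12 / 0.25
  area <- sum(gt$interior_mask)
  expect_gt(area, 0.8^2 * pi * r_px^2)
  expect_lt(area, 1.2^2 * pi * r_px^2)
  # full-frame winding-number rasterisation oracle
  idx <- expand.grid(x = seq_len(gt$dim[1]), y = seq_len(gt$dim[2]))
  inside <- pip_oracle(idx$x, idx$y, gt$contour)
  oracle_mask <- matrix(inside, gt$dim[1], gt$dim[2])
  expect_lt(mean(oracle_mask != gt$interior_mask), 1e-3)  # boundary pixels only
})

test_that("geometry rejects invalid parameters", {
  expect_error(generate_fibre_geometry(3, pixel_size = 0.2),
               class = "glut4_invalid_parameter")
  expect_error(generate_fibre_geometry(30, pixel_size = -1),
               class = "glut4_invalid_parameter")
  expect_error(generate_fibre_geometry(30, irregularity = 1.2),
               class = "glut4_invalid_parameter")
})

test_that("plant_spots delivers exact counts, valid classes and in-fibre centres", {
  gt <- generate_fibre_geometry(20, irregularity = 0.1, pixel_size = 0.2, seed = 3)
  gt <- plant_spots(gt, n_large = 10, n_small = 0, seed = 4)
  expect_equal(nrow(gt$spots), 10)
  expect_true(all(gt$spots$class == "large"))
  expect_true(all(gt$spots$diameter_um > 1.05))
  # centres inside the contour
  px <- round(gt$spots$x); py <- round(gt$spots$y)
  expect_true(all(gt$interior_mask[cbind(px, py)]))
  # the 1 um class rule with the 0.05 um guard band
  gt2 <- plant_spots(gt, 5, 20, seed = 9)
  expect_true(all(abs(gt2$spots$diameter_um - 1) > 0.05))
  expect_identical(gt2$spots$class,
                   ifelse(gt2$spots$diameter_um > 1, "large", "small"))
})

test_that("peripheral placement respects the 1 um depth bound (polyline oracle)", {
  gt <- generate_fibre_geometry(15, irregularity = 0.15, pixel_size = 0.25, seed = 5)
  gt <- plant_spots(gt, 6, 12, peripheral_fraction = 1, perinuclear_fraction = 0,
                    seed = 6)
  d_oracle <- polyline_dist_oracle(as.matrix(gt$spots[, c("x", "y")]),
                                   gt$contour) * gt$pixel_size
  expect_true(all(d_oracle <= 1 + 0.02))
  expect_equal(gt$spots$radial_depth_um, d_oracle, tolerance = 0.02)
})

test_that("empty spot request renders a background-only GLUT4 channel", {
  gt <- generate_fibre_geometry(10, irregularity = 0, pixel_size = 0.25, seed = 7)
  gt <- plant_spots(gt, 0, 0, seed = 8)
  expect_equal(nrow(gt$spots), 0)
  img <- render_image(gt, psf_sigma = 0, noise = list(gaussian_sd = 0))
  # no pixel above the peripheral background ceiling
  ceiling_val <- 200 + gt$background_level * (1 + gt$peripheral_gradient)
  expect_lte(max(img$channels$glut4), ceiling_val + 1)
})

test_that("rendered spot area matches the disk closed form without PSF", {
  gt <- generate_fibre_geometry(10, irregularity = 0, pixel_size = 0.2, seed = 9)
  gt$spots <- data.frame(x = gt$centre[1], y = gt$centre[2], diameter_um = 2,
                         class = "large", radial_depth_um = NA, amplitude = 8000)
  img <- render_image(gt, psf_sigma = 0, noise = list(gaussian_sd = 0))
  bright <- img$channels$glut4 > 200 + gt$background_level * (1 + gt$peripheral_gradient)
  expect_equal(sum(bright) * 0.2^2, pi, tolerance = 0.05)
})

test_that("rendering is deterministic with noise off and MHCI separates fibre types", {
  gt <- generate_fibre_geometry(10, irregularity = 0.1, pixel_size = 0.25,
                                seed = 10, fibre_type = "I")
  i1 <- render_image(gt, psf_sigma = 0.2, noise = list(gaussian_sd = 0))
  i2 <- render_image(gt, psf_sigma = 0.2, noise = list(gaussian_sd = 0))
  expect_identical(i1$channels, i2$channels)
  gt2 <- gt; gt2$fibre_type <- "II"
  i3 <- render_image(gt2, psf_sigma = 0.2, noise = list(gaussian_sd = 0))
  expect_gt(mean(i1$channels$mhc1[gt$interior_mask]),
            mean(i3$channels$mhc1[gt$interior_mask]))
})

test_that("study generation follows the sampling design and plants count effects", {
  cfg <- synth_study_config(
    n_subjects_per_mode = 2, modes = "ET", fibres_per_section_per_type = 5,
    replicates = 3, radius_um_range = c(10, 11), pixel_size = 0.3,
    n_large_mean = 20, n_small_mean = 5,
    effect_sizes = list(large_count = 0.3, whole_intensity = 0,
                        large_size = 0, small_size = 0,
                        peripheral_intensity = 0),
    noise = list(subject_cv = 0, fibre_cv = 0), seed = 31)
  dir <- withr::local_tempdir()
  res <- generate_study(cfg, dir, write_images = FALSE)
  # 3 replicates x 5 fibres x 2 types = 30 images per subject per timepoint
  counts <- table(res$manifest$subject_id, res$manifest$timepoint)
  expect_true(all(counts == 30))
  # planted +30% large-spot count visible in the ground-truth sidecars
  n_large <- vapply(res$truths, function(t) sum(t$spots$class == "large"),
                    numeric(1))
  tp <- res$manifest$timepoint[match(names(n_large), res$manifest$image_path)]
  ratio <- mean(n_large[tp == "post"]) / mean(n_large[tp == "pre"])
  # 60 Poisson(20)-ish draws per arm: ~4% sampling SE on the ratio
  expect_equal(ratio, 1.3, tolerance = 0.12)
})

test_that("study config validates counts and effect sizes", {
  expect_error(synth_study_config(n_subjects_per_mode = 0),
               class = "glut4_invalid_parameter")
  expect_error(synth_study_config(effect_sizes = list(large_count = -2)),
               class = "glut4_invalid_parameter")
})
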