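# Snake segmentation of the dystrophin ring, mask construction, fibre typing.

test_that("initialisation encloses the ring and follows the largest object", {
  fx <- ring_fixture()
  init <- initial_contour(fx$img$channels$dystrophin)
  # every ground-truth contour vertex strictly inside the init polygon
  inside <- pip_oracle(fx$gt$contour[, 1], fx$gt$contour[, 2], init$vertices)
  expect_true(all(inside))
  # blank image -> segmentation failure
  expect_error(initial_contour(matrix(0, 64, 64)),
               class = "glut4_segmentation_failure")
  # two rings: initialisation picks the larger
  gt_small <- generate_fibre_geometry(6, irregularity = 0, pixel_size = 0.25,
                                      seed = 2)
  img2 <- render_image(gt_small, psf_sigma = 0, noise = list(gaussian_sd = 0))
  big <- matrix(150, 400, 400)
  sub <- img2$channels$dystrophin
  big[1:nrow(sub), 1:ncol(sub)] <- sub
  gt_big <- generate_fibre_geometry(20, irregularity = 0, pixel_size = 0.25,
                                    seed = 3)
  img3 <- render_image(gt_big, psf_sigma = 0, noise = list(gaussian_sd = 0))
  off <- c(120, 120)
  d3 <- dim(img3$channels$dystrophin)
  big[off[1] + 1:d3[1] - 1, off[2] + 1:d3[2] - 1] <-
    pmax(big[off[1] + 1:d3[1] - 1, off[2] + 1:d3[2] - 1],
         img3$channels$dystrophin)
  init2 <- initial_contour(big)
  # centroid of the init near the larger ring's centre
  cen <- colMeans(init2$vertices)
  expect_lt(sqrt(sum((cen - (gt_big$centre + off - 1))^2)), 10)
})

test_that("snake converges onto the midline of a noiseless ring", {
  fx <- ring_fixture()
  cfg <- pipeline_config()
  init <- initial_contour(fx$img$channels$dystrophin, cfg$snake_n_vertices)
  sc <- evolve_snake(fx$img$channels$dystrophin, init, cfg)
  expect_true(sc$convergence_report$converged)
  err <- dist_to_polyline(sc$vertices, fx$gt$contour)
  expect_lt(mean(err), 0.5)
  # energy non-increasing across iterations on the noiseless input
  e <- sc$convergence_report$energy
  expect_true(all(diff(e) <= abs(e[1]) * 1e-6))
  # restarting from the converged contour moves below tolerance immediately
  sc2 <- evolve_snake(fx$img$channels$dystrophin, sc, cfg)
  expect_lte(sc2$convergence_report$iterations, 2L)
})

test_that("snake stays accurate under noise (SNR 5, fixed seed)", {
  fx <- ring_fixture()
  img <- render_image(fx$gt, psf_sigma = 0.2,
                      noise = list(gaussian_sd = 1800), seed = 42)
  cfg <- pipeline_config()
  init <- initial_contour(img$channels$dystrophin, cfg$snake_n_vertices)
  sc <- suppressWarnings(evolve_snake(img$channels$dystrophin, init, cfg))
  err <- dist_to_polyline(sc$vertices, fx$gt$contour)
  expect_lt(mean(err), 1.5)
})

test_that("segmentation is equivariant to 90-degree rotation", {
  gt <- generate_fibre_geometry(12, irregularity = 0.15, pixel_size = 0.25,
                                seed = 13)
  img <- render_image(gt, psf_sigma = 0.25, noise = list(gaussian_sd = 0))
  cfg <- pipeline_config()
  dys <- img$channels$dystrophin
  sc <- evolve_snake(dys, initial_contour(dys, cfg$snake_n_vertices), cfg)
  # rotate 90 deg: (x, y) -> (y, n + 1 - x) for an n x m matrix
  rot <- t(dys)[, nrow(dys):1]
  scr <- evolve_snake(rot, initial_contour(rot, cfg$snake_n_vertices), cfg)
  # map rotated vertices back: x' = n + 1 - y_r, y' = x_r
  back <- cbind(nrow(dys) + 1 - scr$vertices[, 2], scr$vertices[, 1])
  hausdorff <- max(c(dist_to_polyline(back, sc$vertices),
                     dist_to_polyline(sc$vertices, back)))
  expect_lt(hausdorff, 0.5)
})

test_that("masks partition the image and the band matches the annulus area", {
  fx <- ring_fixture()
  cfg <- pipeline_config()
  roi <- segment_fibre(fx$img, cfg)
  # 2.5 px halfwidth -> 5 px total thickness: area ~ 2*pi*R*5
  r_px <- 30 / 0.2
  expect_equal(sum(roi$pm_band_mask), 2 * pi * r_px * 5, tolerance = 0.03)
  # partition: band, intracellular, exterior disjoint and exhaustive
  ex <- !(roi$pm_band_mask | roi$intracellular_mask)
  expect_false(any(roi$pm_band_mask & roi$intracellular_mask))
  expect_equal(sum(roi$pm_band_mask) + sum(roi$intracellular_mask) + sum(ex),
               prod(dim(fx$img$channels$glut4)))
  # tiny fibre fully covered by the band -> degenerate error
  tiny <- new_contour_for_test(r_px = 2, dim = c(32, 32))
  expect_error(make_masks(tiny, c(32, 32), 0.2, band_halfwidth_px = 2.5),
               class = "glut4_degenerate_fibre")
})

test_that("fibre typing recovers planted types from bimodal MHCI means", {
  means <- c(rnorm(5, 9000, 200), rnorm(5, 900, 100))
  types <- classify_fibre_type(means, "batch_otsu")
  expect_identical(types, rep(c("I", "II"), each = 5))
  expect_error(classify_fibre_type(5000, "batch_otsu"),
               class = "glut4_insufficient_data")
  expect_identical(classify_fibre_type(5000, "fixed", threshold = 4000), "I")
  # construction check on rendered channels
  fx <- small_fibre_fixture()
  expect_gt(mhc1_mean(fx$img$channels$mhc1, fx$roi), 8000)  # type I render
})
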