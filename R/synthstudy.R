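# Whole-study synthetic dataset generation: subjects x training modes x
# timepoints x replicate sections x fibres, with configurable pre-to-post
# effect sizes written into the ground truth.

#' Configuration for a synthetic training study
#'
#' Defaults mirror the study design: 8 subjects per training mode (ET and
#' SIT), three replicate sections per subject and timepoint, five fibres per
#' type per section — 30 images per subject per timepoint. Default effect
#' sizes are the training responses the method is meant to resolve: +15%
#' whole-fibre GLUT4 intensity, +30% large-spot count, +10% large-spot mean
#' size (area), +17% small-spot mean size, no small-count change, and a
#' peripheral (PM-adjacent) intensity increase.
#'
#' @param n_subjects_per_mode subjects per training mode (>= 1).
#' @param modes training-mode labels.
#' @param fibres_per_section_per_type fibres of each type per section.
#' @param replicates replicate sections per subject/timepoint.
#' @param effect_sizes named list of fractional pre-to-post changes:
#'   `whole_intensity`, `large_count`, `large_size`, `small_count`,
#'   `small_size`, `peripheral_intensity`. All must be finite and > -1.
#' @param noise list: `gaussian_sd` (a.u.), `poisson` (logical),
#'   `subject_cv`, `fibre_cv` (lognormal coefficients of variation of the
#'   subject and fibre intensity/abundance factors).
#' @param psf_sigma_um Gaussian PSF sigma, micrometres.
#' @param pixel_size micrometres per pixel.
#' @param radius_um_range fibre radius range, micrometres.
#' @param irregularity contour perturbation amplitude.
#' @param n_large_mean,n_small_mean mean planted spot counts per fibre.
#' @param peripheral_fraction,perinuclear_fraction spot placement fractions.
#' @param seed master seed; per-image seeds are derived by stable hashing.
#' @return object of class `synth_study_config`.
#' @export
synth_study_config <- function(n_subjects_per_mode = 8L,
                               modes = c("ET", "SIT"),
                               fibres_per_section_per_type = 5L,
                               replicates = 3L,
                               effect_sizes = list(),
                               noise = list(),
                               psf_sigma_um = 0.2,
                               pixel_size = 0.2,
                               radius_um_range = c(25, 35),
                               irregularity = 0.12,
                               n_large_mean = 12,
                               n_small_mean = 60,
                               peripheral_fraction = 0.4,
                               perinuclear_fraction = 0.2,
                               seed = 1L) {
  eff <- utils::modifyList(list(
    whole_intensity = 0.15, large_count = 0.30, large_size = 0.10,
    small_count = 0.0, small_size = 0.17, peripheral_intensity = 0.25
  ), effect_sizes)
  nz <- utils::modifyList(list(
    gaussian_sd = 250, poisson = FALSE, subject_cv = 0.08, fibre_cv = 0.06
  ), noise)
  counts <- c(n_subjects_per_mode = n_subjects_per_mode,
              fibres_per_section_per_type = fibres_per_section_per_type,
              replicates = replicates)
  if (any(counts < 1)) {
    abort_glut4(paste0("counts must all be >= 1: ",
                       paste(names(counts)[counts < 1], collapse = ", ")),
                "glut4_invalid_parameter")
  }
  ev <- unlist(eff)
  if (any(!is.finite(ev)) || any(ev <= -1)) {
    abort_glut4("effect sizes must be finite fractions > -1",
                "glut4_invalid_parameter")
  }
  structure(list(
    n_subjects_per_mode = as.integer(n_subjects_per_mode), modes = modes,
    fibres_per_section_per_type = as.integer(fibres_per_section_per_type),
    replicates = as.integer(replicates), effect_sizes = eff, noise = nz,
    psf_sigma_um = psf_sigma_um, pixel_size = pixel_size,
    radius_um_range = radius_um_range, irregularity = irregularity,
    n_large_mean = n_large_mean, n_small_mean = n_small_mean,
    peripheral_fraction = peripheral_fraction,
    perinuclear_fraction = perinuclear_fraction,
    seed = as.integer(seed)
  ), class = "synth_study_config")
}

#' Generate a full synthetic study: images, ground truth and manifest
#'
#' For every subject and timepoint, `replicates x fibres_per_section_per_type
#' x 2` fibre images are generated (types I and II). Post-training ground
#' truths have their spot counts/sizes and intensities scaled by the
#' configured effect sizes. Images are written as multi-page TIFFs with JSON
#' calibration sidecars, ground truth as `*.truth.json` sidecars, and the
#' study manifest as CSV.
#'
#' @param config a [synth_study_config()].
#' @param output_dir directory to create the dataset in.
#' @param write_images write TIFF files (set `FALSE` to generate ground truth
#'   and manifest only, e.g. for truth-level checks).
#' @return invisibly, a list with `manifest` (data.frame), `truths` (named
#'   list of `ground_truth` keyed by image path) and `dir`.
#' @export
generate_study <- function(config, output_dir, write_images = TRUE) {
  stopifnot(inherits(config, "synth_study_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  eff <- config$effect_sizes
  nz <- config$noise
  rows <- list(); truths <- list()
  for (mode in config$modes) {
    for (s in seq_len(config$n_subjects_per_mode)) {
      subject_id <- sprintf("%s%02d", mode, s)
      sseed <- derive_seed(config$seed, "subject", mode, s)
      subj <- withr::with_seed(sseed, {
        list(int = exp(stats::rnorm(1, 0, nz$subject_cv)),
             abund = exp(stats::rnorm(1, 0, nz$subject_cv)))
      })
      for (tp in c("pre", "post")) {
        post <- tp == "post"
        mult <- list(
          intensity = subj$int * (1 + if (post) eff$whole_intensity else 0),
          large_count = subj$abund * (1 + if (post) eff$large_count else 0),
          small_count = subj$abund * (1 + if (post) eff$small_count else 0),
          large_diam = sqrt(1 + if (post) eff$large_size else 0),
          small_diam = sqrt(1 + if (post) eff$small_size else 0),
          peri = 1 + if (post) eff$peripheral_intensity else 0
        )
        for (rep_i in seq_len(config$replicates)) {
          for (ft in c("I", "II")) {
            for (f in seq_len(config$fibres_per_section_per_type)) {
              iseed <- derive_seed(config$seed, "image", mode, s, tp, rep_i, ft, f)
              truth <- withr::with_seed(iseed, {
                radius <- stats::runif(1, config$radius_um_range[1],
                                       config$radius_um_range[2])
                fibre_cv <- exp(stats::rnorm(1, 0, nz$fibre_cv))
                nl <- stats::rpois(1, config$n_large_mean * mult$large_count * fibre_cv)
                ns <- stats::rpois(1, config$n_small_mean * mult$small_count * fibre_cv)
                list(radius = radius, fibre_cv = fibre_cv, nl = nl, ns = ns)
              })
              gt <- generate_fibre_geometry(
                truth$radius, config$irregularity, config$pixel_size,
                seed = derive_seed(iseed, "geom"), fibre_type = ft
              )
              gt$background_level <- 1500 * mult$intensity * truth$fibre_cv
              gt$peripheral_gradient <- gt$peripheral_gradient * mult$peri
              gt <- plant_spots(
                gt, truth$nl, truth$ns,
                large_diam = c(1.6 * mult$large_diam, 0.3),
                small_diam = c(0.65 * mult$small_diam, 0.1),
                peripheral_fraction = config$peripheral_fraction,
                perinuclear_fraction = config$perinuclear_fraction,
                seed = derive_seed(iseed, "spots")
              )
              fname <- sprintf("%s_%s_r%d_%s_f%02d.tif", subject_id, tp,
                               rep_i, ft, f)
              path <- file.path(output_dir, fname)
              if (write_images) {
                img <- render_image(
                  gt, psf_sigma = config$psf_sigma_um,
                  noise = list(gaussian_sd = nz$gaussian_sd,
                               poisson = nz$poisson),
                  seed = derive_seed(iseed, "noise")
                )
                img$image_id <- fname
                write_image(img, path)
              }
              write_truth_sidecar(gt, paste0(path, ".truth.json"))
              truths[[fname]] <- gt
              rows[[length(rows) + 1L]] <- data.frame(
                subject_id = subject_id, mode = mode, timepoint = tp,
                replicate = rep_i, fibre_index = f, fibre_type = ft,
                image_path = fname, stringsAsFactors = FALSE
              )
            }
          }
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(output_dir, "manifest.csv"))
  jsonlite::write_json(
    list(generator = "glut4layers", seed = config$seed,
         config = unclass(config)),
    file.path(output_dir, "study.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(list(manifest = manifest, truths = truths, dir = output_dir))
}

write_truth_sidecar <- function(truth, path) {
  out <- list(
    contour = round(unname(truth$contour), 3),
    fibre_type = truth$fibre_type,
    nuclei = truth$nuclei,
    spots = truth$spots,
    background_level = truth$background_level,
    peripheral_gradient = truth$peripheral_gradient,
    peripheral_scale_um = truth$peripheral_scale_um,
    pixel_size = truth$pixel_size, seed = truth$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a ground-truth sidecar written by [generate_study()]
#' @param path `*.truth.json` path.
#' @return list with contour matrix, spots and nuclei data.frames, etc.
#' @export
read_truth_sidecar <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$contour <- matrix(unlist(x$contour), ncol = 2, byrow = FALSE)
  x$spots <- as.data.frame(x$spots)
  x$nuclei <- as.data.frame(x$nuclei)
  x
}
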