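# Stage orchestration: simulate a dataset, quantify every image in a study
# (segmentation -> layers -> spots -> metrics, with per-image QC), and run
# the statistics stage on the resulting tables. These functions are the
# programmatic equivalents of the command-line front end in
# inst/scripts/glut4-pipeline.R.

#' Simulate a synthetic study dataset
#'
#' Thin wrapper over [generate_study()] that also records a run record
#' (resolved configuration, seed, software version, timestamp).
#'
#' @param config a [synth_study_config()].
#' @param output_dir dataset directory to create.
#' @return invisibly, the [generate_study()] result.
#' @export
simulate_study <- function(config, output_dir) {
  res <- generate_study(config, output_dir)
  write_run_record(output_dir, command = "simulate",
                   config = unclass(config), seed = config$seed)
  invisible(res)
}

#' Quantify every image of a study
#'
#' For each manifest row: read the image, segment the fibre (snake on
#' dystrophin), build the PM band and concentric layers, preprocess the
#' GLUT4 channel, detect and classify spots, assign them to layers, and
#' compute whole-fibre and per-layer metrics. Fibre types are classified
#' batch-wise from the MHCI channel (Otsu over per-fibre means) when an MHCI
#' channel is present, otherwise taken from the manifest. Images that fail
#' (non-convergence, degenerate fibre, ...) are recorded in a QC table and
#' excluded; more than `max_failure_rate` failures aborts the run.
#'
#' @param dataset_dir directory containing `manifest.csv` and images.
#' @param cfg a [pipeline_config()].
#' @param output_dir where to write `fibre_metrics.csv`, `layer_metrics.csv`,
#'   `spots.csv`, `qc.csv` (default: `dataset_dir`).
#' @param max_failure_rate run-level QC threshold (default 0.2).
#' @return invisibly, list with `fibre_metrics`, `layer_metrics`, `spots`,
#'   `qc` data.frames.
#' @export
quantify_study <- function(dataset_dir, cfg = pipeline_config(),
                           output_dir = dataset_dir,
                           max_failure_rate = 0.2) {
  manifest <- read_manifest(file.path(dataset_dir, "manifest.csv"))
  n <- nrow(manifest)
  results <- vector("list", n)
  qc <- data.frame(image_path = manifest$image_path,
                   status = "ok", reason = "", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    path <- file.path(dataset_dir, manifest$image_path[i])
    results[[i]] <- tryCatch(
      quantify_image(read_image(path), cfg),
      glut4_error = function(e) e, error = function(e) e
    )
    if (inherits(results[[i]], "condition")) {
      qc$status[i] <- "failed"
      qc$reason[i] <- conditionMessage(results[[i]])
    }
  }
  fail_rate <- mean(qc$status == "failed")
  if (fail_rate > max_failure_rate) {
    abort_glut4(sprintf("QC failure rate %.0f%% exceeds %.0f%%",
                        100 * fail_rate, 100 * max_failure_rate),
                "glut4_qc_error")
  }
  ok <- which(qc$status == "ok")
  # batch fibre typing from measured MHCI means where available
  mhc_means <- vapply(ok, function(i) {
    r <- results[[i]]
    if (is.null(r$mhc1_mean)) NA_real_ else r$mhc1_mean
  }, numeric(1))
  types <- manifest$fibre_type[ok]
  if (all(is.finite(mhc_means)) && length(ok) >= 2) {
    types <- classify_fibre_type(mhc_means, "batch_otsu")
  }
  fibre_rows <- list(); layer_rows <- list(); spot_rows <- list()
  for (j in seq_along(ok)) {
    i <- ok[j]
    r <- results[[i]]
    keys <- manifest[i, c("subject_id", "mode", "timepoint", "replicate",
                          "fibre_index"), drop = FALSE]
    keys$fibre_type <- types[j]
    keys$image_path <- manifest$image_path[i]
    fibre_rows[[j]] <- cbind(keys, r$fibre_metrics, row.names = NULL)
    layer_rows[[j]] <- cbind(keys[rep(1, nrow(r$layer_metrics)), ],
                             r$layer_metrics, row.names = NULL)
    st <- spot_table(r$spots)
    if (nrow(st) > 0) {
      spot_rows[[j]] <- cbind(keys[rep(1, nrow(st)), ], st, row.names = NULL)
    }
  }
  out <- list(
    fibre_metrics = do.call(rbind, fibre_rows),
    layer_metrics = do.call(rbind, layer_rows),
    spots = if (length(spot_rows)) do.call(rbind, spot_rows) else NULL,
    qc = qc
  )
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$fibre_metrics,
                   file.path(output_dir, "fibre_metrics.csv"), row.names = FALSE)
  utils::write.csv(out$layer_metrics,
                   file.path(output_dir, "layer_metrics.csv"), row.names = FALSE)
  if (!is.null(out$spots)) {
    utils::write.csv(out$spots, file.path(output_dir, "spots.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(qc, file.path(output_dir, "qc.csv"), row.names = FALSE)
  write_run_record(output_dir, command = "quantify", config = unclass(cfg),
                   seed = NA,
                   manifest_hash = unname(tools::md5sum(
                     file.path(dataset_dir, "manifest.csv"))))
  invisible(out)
}

#' Quantify a single calibrated image
#'
#' Runs the full per-image pipeline and returns the intermediate objects
#' alongside the metric tables.
#'
#' @param img a [calibrated_image()].
#' @param cfg a [pipeline_config()].
#' @return list with `roi`, `layers`, `spots` (layer-assigned `spot_set`),
#'   `fibre_metrics` (one row), `layer_metrics`, `mhc1_mean`.
#' @export
quantify_image <- function(img, cfg = pipeline_config()) {
  roi <- segment_fibre(img, cfg)
  layers <- build_layers(roi, n_layers = cfg$n_layers,
                         thickness_um = cfg$layer_thickness_um)
  filtered <- preprocess_glut4(img$channels$glut4, cfg)
  region <- roi$pm_band_mask | roi$intracellular_mask
  spots <- detect_spots(filtered, region,
                        intensity_threshold = cfg$spot_intensity_threshold,
                        min_area_px = cfg$spot_min_area_px,
                        pixel_size = img$pixel_size,
                        boundary_um = cfg$size_class_boundary_um,
                        fibre_id = img$image_id)
  spots <- assign_layers(spots, layers)
  fibre_area <- sum(roi$intracellular_mask) * img$pixel_size^2
  fm <- cbind(
    data.frame(mean_intensity = fibre_mean_intensity(img$channels$glut4, roi)),
    fibre_spot_metrics(spots, fibre_area)
  )
  lm <- layer_metrics(img$channels$glut4, spots, layers)
  mh <- if (!is.null(img$channels$mhc1)) mhc1_mean(img$channels$mhc1, roi) else NULL
  list(roi = roi, layers = layers, spots = spots, fibre_metrics = fm,
       layer_metrics = lm, mhc1_mean = mh)
}

#' Run the statistics stage on quantified metrics
#'
#' Reads `fibre_metrics.csv` and `layer_metrics.csv` from `metrics_dir`,
#' runs [analyze_study()], and writes `report.json` / `report.txt`.
#'
#' @param metrics_dir directory with the metrics CSVs.
#' @param output_dir report directory (default `metrics_dir`).
#' @param alpha significance level.
#' @param max_layer highest layer index analysed (default: layers complete
#'   in every image).
#' @return the `glut4_report`, invisibly.
#' @export
run_stats <- function(metrics_dir, output_dir = metrics_dir, alpha = 0.05,
                      max_layer = NULL) {
  fpath <- file.path(metrics_dir, "fibre_metrics.csv")
  lpath <- file.path(metrics_dir, "layer_metrics.csv")
  for (p in c(fpath, lpath)) {
    if (!file.exists(p)) {
      abort_glut4(paste0("metrics file not found: ", p,
                         " (run quantify_study first)"), "glut4_io_error")
    }
  }
  fm <- utils::read.csv(fpath, stringsAsFactors = FALSE)
  lm <- utils::read.csv(lpath, stringsAsFactors = FALSE)
  if (is.null(max_layer)) {
    complete <- lm[lm$layer_index >= 1 & lm$layer_index <= max(lm$layer_index) - 1, ]
    by_layer <- tapply(complete$complete, complete$layer_index,
                       function(x) all(x, na.rm = TRUE))
    full <- as.integer(names(by_layer))[which(by_layer)]
    max_layer <- if (length(full)) max(full) else 1L
  }
  report <- analyze_study(fm, lm, alpha = alpha, max_layer = max_layer)
  write_report(report, output_dir)
  invisible(report)
}

write_run_record <- function(dir, command, config, seed,
                             manifest_hash = NULL) {
  rec <- list(
    command = command, config = config, seed = seed,
    manifest_hash = manifest_hash,
    package_version = as.character(utils::packageVersion("glut4layers")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(rec, file.path(dir, paste0("run_", command, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(rec)
}
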