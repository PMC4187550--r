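# The study's inferential pipeline: paired t tests, mixed repeated-measures
# ANOVA (training within, mode between), two-within-factor repeated-measures
# ANOVA (training x layer), Bonferroni adjustment, and the decision cascade
# tying them together.

#' Paired t test
#'
#' Two-sided paired t on `post - pre`: `t = mean(d) / (sd(d) / sqrt(n))`,
#' `df = n - 1`. Computed from the closed form (via [stats::pt()]) so the
#' degenerate all-zero-differences case can be represented as
#' `t = 0, p = 1` (no evidence of change).
#'
#' @param pre,post numeric vectors of equal length `n >= 2`, paired by
#'   subject.
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) {
    abort_glut4("pre and post must have equal length", "glut4_invalid_parameter")
  }
  n <- length(pre)
  if (n < 2) abort_glut4("paired t needs n >= 2", "glut4_undefined_statistic")
  d <- post - pre
  sdd <- stats::sd(d)
  md <- mean(d)
  if (sdd == 0) {
    if (md == 0) return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    abort_glut4("zero variance of differences with non-zero mean",
                "glut4_undefined_statistic")
  }
  t <- md / (sdd / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1), mean_diff = md)
}

#' Bonferroni adjustment
#'
#' `adjusted = min(1, m * p)` with `m` defaulting to the number of p-values
#' but allowed to be larger (comparisons counted but not reported).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param m number of comparisons, `m >= length(pvals)`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (length(pvals) < 1 || any(!is.finite(pvals)) ||
      any(pvals < 0) || any(pvals > 1)) {
    abort_glut4("p-values must lie in [0, 1]", "glut4_invalid_parameter")
  }
  if (m < length(pvals)) {
    abort_glut4("m must be >= length(pvals)", "glut4_invalid_parameter")
  }
  stats::p.adjust(pvals, method = "bonferroni", n = m)
}

# -- design validation helpers ----------------------------------------------

check_complete_balanced <- function(df, subject, factors) {
  counts <- table(df[[subject]], interaction(df[factors], drop = FALSE))
  if (any(counts == 0)) {
    abort_glut4("design has missing cells (no imputation is performed)",
                "glut4_design_error")
  }
  if (any(counts > 1)) {
    abort_glut4("design has duplicated cells; aggregate to one value per cell first",
                "glut4_design_error")
  }
  invisible(TRUE)
}

#' One-within repeated-measures ANOVA: training only
#'
#' Paired design for a single-arm study (one training mode): fits
#' `value ~ training + Error(subject/training)`.
#'
#' @param df data.frame with columns `subject`, `training`, `value`.
#' @return an `anova_table`.
#' @export
rm_anova_one_within <- function(df) {
  need <- c("subject", "training", "value")
  if (!all(need %in% names(df))) {
    abort_glut4(paste0("need columns: ", paste(need, collapse = ", ")),
                "glut4_invalid_parameter")
  }
  df$subject <- factor(df$subject); df$training <- factor(df$training)
  check_complete_balanced(df, "subject", "training")
  fit <- stats::aov(value ~ training + Error(subject / training), data = df)
  tab <- tidy_aov_error(fit)
  attr(tab, "design") <- list(within = "training",
                              n_subjects = nlevels(df$subject))
  tab
}

#' Mixed repeated-measures ANOVA: training (within) x mode (between)
#'
#' One value per subject and timepoint; each subject belongs to one training
#' mode. Fits `value ~ mode * training + Error(subject/training)` with
#' [stats::aov()] and returns the tidy effect table with the
#' subject-within-mode and subject-by-training error strata.
#'
#' @param df data.frame with columns `subject`, `mode`, `training`, `value`.
#' @return an `anova_table`: data.frame with effect, df, ss, ms, f, p,
#'   stratum; design descriptor in attributes.
#' @export
mixed_anova <- function(df) {
  need <- c("subject", "mode", "training", "value")
  if (!all(need %in% names(df))) {
    abort_glut4(paste0("need columns: ", paste(need, collapse = ", ")),
                "glut4_invalid_parameter")
  }
  df$subject <- factor(df$subject); df$mode <- factor(df$mode)
  df$training <- factor(df$training)
  # each subject in exactly one mode
  sm <- unique(df[c("subject", "mode")])
  if (anyDuplicated(sm$subject)) {
    abort_glut4("a subject appears in more than one mode", "glut4_design_error")
  }
  check_complete_balanced(df, "subject", "training")
  per_mode <- table(sm$mode)
  if (any(per_mode < 2)) {
    abort_glut4("need >= 2 subjects per mode", "glut4_design_error")
  }
  if (length(unique(per_mode)) != 1L) {
    abort_glut4(paste0("unbalanced groups: ",
                       paste(sprintf("%s=%d", names(per_mode), per_mode),
                             collapse = ", ")), "glut4_design_error")
  }
  fit <- stats::aov(value ~ mode * training + Error(subject / training),
                    data = df)
  tab <- tidy_aov_error(fit)
  attr(tab, "design") <- list(within = "training", between = "mode",
                              n_subjects = nrow(sm),
                              n_per_mode = as.vector(per_mode))
  tab
}

#' Two-within-factor repeated-measures ANOVA: training x layer
#'
#' Every subject measured at every training x layer combination. Fits
#' `value ~ training * layer + Error(subject/(training*layer))`, giving each
#' within effect its own subject-interaction error stratum.
#'
#' @param df data.frame with columns `subject`, `training`, `layer`, `value`.
#' @return an `anova_table` (see [mixed_anova()]).
#' @export
rm_anova_two_within <- function(df) {
  need <- c("subject", "training", "layer", "value")
  if (!all(need %in% names(df))) {
    abort_glut4(paste0("need columns: ", paste(need, collapse = ", ")),
                "glut4_invalid_parameter")
  }
  df$subject <- factor(df$subject); df$training <- factor(df$training)
  df$layer <- factor(df$layer)
  check_complete_balanced(df, "subject", c("training", "layer"))
  fit <- stats::aov(value ~ training * layer + Error(subject / (training * layer)),
                    data = df)
  tab <- tidy_aov_error(fit)
  attr(tab, "design") <- list(within = c("training", "layer"),
                              n_subjects = length(unique(df$subject)),
                              n_layers = nlevels(df$layer))
  tab
}

# flatten summary(aov-with-Error) into one data.frame
tidy_aov_error <- function(fit) {
  s <- summary(fit)
  rows <- list()
  for (stratum in names(s)) {
    st <- s[[stratum]][[1]]
    eff <- trimws(rownames(st))
    for (i in seq_along(eff)) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = eff[i], df = st$Df[i], ss = st$`Sum Sq`[i],
        ms = st$`Mean Sq`[i],
        f = if ("F value" %in% names(st)) st$`F value`[i] else NA_real_,
        p = if ("Pr(>F)" %in% names(st)) st$`Pr(>F)`[i] else NA_real_,
        stratum = sub("^Error: ", "", stratum), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Repeated-measures ANOVA\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

# pull one effect's F-test from an anova_table
anova_effect <- function(tab, effect) {
  row <- tab[trimws(tab$effect) == effect & !is.na(tab$f), , drop = FALSE]
  if (nrow(row) == 0) {
    row <- tab[trimws(tab$effect) == effect, , drop = FALSE][1, , drop = FALSE]
  }
  row[1, , drop = FALSE]
}

#' Run the study's inferential cascade
#'
#' Whole-fibre metrics (mean intensity, large/small spot density, mean
#' large/small spot size) are aggregated to subject x timepoint means and
#' analysed with the training x mode mixed ANOVA; significant main effects
#' get Bonferroni pairwise comparisons. Layered metrics (per-layer mean
#' intensity and large-spot density, fibre types pooled) are aggregated to
#' subject x timepoint x layer means and analysed per training mode with the
#' training x layer within-subject ANOVA; a significant layer main effect
#' triggers Bonferroni pairwise layer comparisons, and a significant
#' training x layer interaction triggers unadjusted within-layer paired t
#' tests to locate the layers in which GLUT4 increased.
#'
#' @param fibre_metrics per-fibre table (see [quantify_study()]): columns
#'   subject_id, mode, timepoint, fibre_type plus metric columns.
#' @param layer_metrics per-fibre-per-layer table: columns subject_id, mode,
#'   timepoint, layer_index, mean_intensity, large_per_area.
#' @param alpha significance level for every gate (default 0.05).
#' @param max_layer highest layer index included in the layered analysis
#'   (default: all complete layers present for every subject).
#' @return a `glut4_report`: list with `whole_fibre` (per metric: anova,
#'   posthoc), `layered` (per mode and metric: anova, layer_posthoc,
#'   within_layer), `tests` (bookkeeping of every test run and its trigger)
#'   and `alpha`.
#' @export
analyze_study <- function(fibre_metrics, layer_metrics, alpha = 0.05,
                          max_layer = NULL) {
  tests <- list()
  note_test <- function(name, trigger, p) {
    tests[[length(tests) + 1L]] <<- data.frame(
      test = name, trigger = trigger, p = p, stringsAsFactors = FALSE)
  }

  whole <- list()
  metrics <- intersect(
    c("mean_intensity", "large_density", "mean_large_size",
      "small_density", "mean_small_size"),
    names(fibre_metrics)
  )
  for (m in metrics) {
    agg <- stats::aggregate(
      fibre_metrics[[m]],
      by = list(subject = fibre_metrics$subject_id,
                mode = fibre_metrics$mode,
                training = fibre_metrics$timepoint),
      FUN = mean, na.rm = TRUE
    )
    names(agg)[4] <- "value"
    tab <- if (length(unique(agg$mode)) >= 2) {
      mixed_anova(agg)
    } else {
      rm_anova_one_within(agg)  # single-arm study: paired design
    }
    note_test(paste0("whole_fibre/", m, "/anova"), "always",
              anova_effect(tab, "training")$p)
    posthoc <- NULL
    p_train <- anova_effect(tab, "training")$p
    if (is.finite(p_train) && p_train < alpha) {
      wide <- split(agg$value, agg$training)
      # pairwise pre/post comparison under the Bonferroni umbrella
      pt <- paired_t(wide$pre[order(agg$subject[agg$training == "pre"])],
                     wide$post[order(agg$subject[agg$training == "post"])])
      posthoc <- data.frame(
        comparison = "post - pre", raw_p = pt$p,
        adjusted_p = bonferroni(pt$p, m = 1L), method = "Bonferroni",
        stringsAsFactors = FALSE
      )
      note_test(paste0("whole_fibre/", m, "/posthoc"),
                "training main effect significant", pt$p)
    }
    whole[[m]] <- list(anova = tab, posthoc = posthoc)
  }

  layered <- list()
  lm_metrics <- intersect(c("mean_intensity", "large_per_area"),
                          names(layer_metrics))
  for (mode in unique(layer_metrics$mode)) {
    sub <- layer_metrics[layer_metrics$mode == mode, , drop = FALSE]
    if (!is.null(max_layer)) {
      sub <- sub[sub$layer_index <= max_layer, , drop = FALSE]
    }
    layered[[mode]] <- list()
    for (m in lm_metrics) {
      agg <- stats::aggregate(
        sub[[m]],
        by = list(subject = sub$subject_id, training = sub$timepoint,
                  layer = sub$layer_index),
        FUN = mean, na.rm = TRUE
      )
      names(agg)[4] <- "value"
      tab <- rm_anova_two_within(agg)
      p_layer <- anova_effect(tab, "layer")$p
      p_int <- anova_effect(tab, "training:layer")$p
      note_test(paste0("layered/", mode, "/", m, "/anova"), "always", p_int)
      layer_posthoc <- NULL
      if (is.finite(p_layer) && p_layer < alpha) {
        layer_posthoc <- pairwise_layers(agg)
        note_test(paste0("layered/", mode, "/", m, "/layer_posthoc"),
                  "layer main effect significant", min(layer_posthoc$adjusted_p))
      }
      within_layer <- NULL
      if (is.finite(p_int) && p_int < alpha) {
        within_layer <- within_layer_t(agg)
        note_test(paste0("layered/", mode, "/", m, "/within_layer_t"),
                  "training x layer interaction significant",
                  min(within_layer$p))
      }
      layered[[mode]][[m]] <- list(anova = tab, layer_posthoc = layer_posthoc,
                                   within_layer = within_layer)
    }
  }
  structure(list(whole_fibre = whole, layered = layered,
                 tests = do.call(rbind, tests), alpha = alpha),
            class = "glut4_report")
}

# Bonferroni-adjusted pairwise paired t tests between layers
# (averaged over training)
pairwise_layers <- function(agg) {
  per <- stats::aggregate(value ~ subject + layer, data = agg, FUN = mean)
  layers <- sort(unique(per$layer))
  combs <- utils::combn(as.character(layers), 2)
  raw <- apply(combs, 2, function(pr) {
    a <- per$value[per$layer == pr[1]][order(per$subject[per$layer == pr[1]])]
    b <- per$value[per$layer == pr[2]][order(per$subject[per$layer == pr[2]])]
    paired_t(a, b)$p
  })
  data.frame(
    comparison = apply(combs, 2, paste, collapse = " vs "),
    raw_p = raw, adjusted_p = bonferroni(raw), method = "Bonferroni",
    stringsAsFactors = FALSE
  )
}

# within-layer paired pre/post t tests (unadjusted, per the study protocol)
within_layer_t <- function(agg) {
  layers <- sort(unique(agg$layer))
  rows <- lapply(layers, function(l) {
    sl <- agg[agg$layer == l, ]
    pre <- sl$value[sl$training == "pre"][order(sl$subject[sl$training == "pre"])]
    post <- sl$value[sl$training == "post"][order(sl$subject[sl$training == "post"])]
    pt <- paired_t(pre, post)
    data.frame(layer = l, t = pt$t, df = pt$df, p = pt$p,
               mean_diff = pt$mean_diff, method = "paired-t-within-layer",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.glut4_report <- function(x, ...) {
  cat(sprintf("<glut4_report> alpha = %g\n", x$alpha))
  cat(sprintf("  whole-fibre metrics analysed: %s\n",
              paste(names(x$whole_fibre), collapse = ", ")))
  for (mode in names(x$layered)) {
    for (m in names(x$layered[[mode]])) {
      el <- x$layered[[mode]][[m]]
      p_int <- anova_effect(el$anova, "training:layer")$p
      cat(sprintf("  %s/%s: training x layer p = %.4g%s\n", mode, m, p_int,
                  if (!is.null(el$within_layer)) " -> within-layer t tests run" else ""))
    }
  }
  cat(sprintf("  tests run: %d\n", nrow(x$tests)))
  invisible(x)
}

#' Write a study report as JSON and readable text
#' @param report a `glut4_report`.
#' @param dir output directory.
#' @return paths of the written files, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jpath <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), jpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE, na = "null")
  tpath <- file.path(dir, "report.txt")
  con <- file(tpath, "w")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  for (m in names(report$whole_fibre)) {
    cat("\n== whole fibre:", m, "==\n")
    print(report$whole_fibre[[m]]$anova)
  }
  for (mode in names(report$layered)) {
    for (m in names(report$layered[[mode]])) {
      cat("\n== layered:", mode, m, "==\n")
      print(report$layered[[mode]][[m]]$anova)
      wl <- report$layered[[mode]][[m]]$within_layer
      if (!is.null(wl)) { cat("within-layer paired t:\n"); print(wl) }
    }
  }
  invisible(c(jpath, tpath))
}
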