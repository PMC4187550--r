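# Paired t, repeated-measures ANOVAs (with brute-force oracle), Bonferroni,
# and the analysis cascade.

test_that("paired t matches the textbook closed form and its symmetries", {
  # d = {1,2,3,4}: t = 2.5 / (1.29099/2) = 3.873, df 3, p ~ 0.0305
  pre <- c(10, 10, 10, 10); post <- c(11, 12, 13, 14)
  r <- paired_t(pre, post)
  expect_equal(r$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(r$df, 3)
  expect_equal(r$p, 0.03047, tolerance = 1e-3)
  # identical vectors: no evidence of change
  r0 <- paired_t(pre, pre)
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)
  # sign-flip antisymmetry
  rs <- paired_t(post, pre)
  expect_equal(rs$t, -r$t); expect_equal(rs$p, r$p)
  expect_error(paired_t(1, 2), class = "glut4_undefined_statistic")
  expect_error(paired_t(c(1, 1), c(3, 3)), class = "glut4_undefined_statistic")
})

test_that("bonferroni caps, scales and preserves order", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 4), 1.0)
  p <- runif(10, 0, 0.099)  # below the cap so ranks stay informative
  adj <- bonferroni(p)
  expect_identical(order(adj), order(p))
  expect_true(all(adj >= p))
  expect_error(bonferroni(1.2), class = "glut4_invalid_parameter")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), class = "glut4_invalid_parameter")
})

test_that("mixed ANOVA matches the brute-force cell-means decomposition", {
  set.seed(101)
  for (rep_i in 1:5) {
    df <- sim_mixed_table(n_per_mode = 4, delta = runif(1, -1, 1))
    tab <- mixed_anova(df)
    o <- oracle_mixed_anova(df)
    get_ss <- function(eff, strat) {
      tab$ss[trimws(tab$effect) == eff & tab$stratum == strat]
    }
    expect_equal(get_ss("mode", "subject"), o$mode, tolerance = 1e-9)
    expect_equal(get_ss("Residuals", "subject"), o$subj_within, tolerance = 1e-9)
    expect_equal(get_ss("training", "subject:training"), o$training,
                 tolerance = 1e-9)
    expect_equal(get_ss("mode:training", "subject:training"), o$interaction,
                 tolerance = 1e-9)
    # SS additivity to the total
    expect_equal(sum(tab$ss), o$total, tolerance = 1e-9)
    # df closed forms
    expect_equal(tab$df[trimws(tab$effect) == "mode"], 1)
    expect_equal(tab$df[tab$stratum == "subject" &
                          trimws(tab$effect) == "Residuals"], 6)
  }
})

test_that("mixed ANOVA degenerate and invalid designs are handled", {
  df <- sim_mixed_table(n_per_mode = 3)
  df$value <- 5
  tab <- mixed_anova(df)
  # SS_total = 0: F ratios are 0/0 and carry no information
  expect_equal(sum(tab$ss), 0, tolerance = 1e-12)
  # missing cell
  expect_error(mixed_anova(df[-1, ]), class = "glut4_design_error")
  # unbalanced groups
  df2 <- sim_mixed_table(n_per_mode = 3)
  drop_subj <- df2$subject == "s01"
  expect_error(mixed_anova(df2[!drop_subj, ]), class = "glut4_design_error")
  # too few subjects per mode
  df3 <- sim_mixed_table(n_per_mode = 1)
  expect_error(mixed_anova(df3), class = "glut4_design_error")
})

test_that("two-within ANOVA matches the oracle with per-effect error strata", {
  set.seed(202)
  for (rep_i in 1:5) {
    df <- sim_two_within_table(n_subjects = 4, n_layers = 3,
                               delta = runif(1, -1, 1), effect_layers = 0:1)
    tab <- rm_anova_two_within(df)
    o <- oracle_two_within(df)
    get_ss <- function(eff, strat) {
      tab$ss[trimws(tab$effect) == eff & tab$stratum == strat]
    }
    expect_equal(get_ss("training", "subject:training"), o$training,
                 tolerance = 1e-9)
    expect_equal(get_ss("layer", "subject:layer"), o$layer, tolerance = 1e-9)
    expect_equal(get_ss("training:layer", "subject:training:layer"),
                 o$interaction, tolerance = 1e-9)
    expect_equal(get_ss("Residuals", "subject:training"), o$err_training,
                 tolerance = 1e-9)
    expect_equal(get_ss("Residuals", "subject:layer"), o$err_layer,
                 tolerance = 1e-9)
    expect_equal(sum(tab$ss), o$total, tolerance = 1e-9)
  }
  # identical layer means -> SS_layer = 0
  df0 <- sim_two_within_table(n_subjects = 3, n_layers = 3)
  df0$value <- ave(df0$value, df0$subject, df0$training)
  tab0 <- rm_anova_two_within(df0)
  expect_equal(tab0$ss[trimws(tab0$effect) == "layer" &
                         tab0$stratum == "subject:layer"], 0, tolerance = 1e-9)
})

test_that("analysis cascade triggers exactly the protocol's tests", {
  set.seed(301)
  # build synthetic metric tables with a layer-restricted training effect
  n_sub <- 8
  fibre <- expand.grid(subject_id = sprintf("s%02d", 1:n_sub),
                       timepoint = c("pre", "post"),
                       fibre_type = c("I", "II"),
                       fibre = 1:3, stringsAsFactors = FALSE)
  fibre$mode <- "ET"
  fibre$mean_intensity <- rnorm(nrow(fibre), 100, 5) +
    ifelse(fibre$timepoint == "post", 15, 0)
  layer <- expand.grid(subject_id = sprintf("s%02d", 1:n_sub),
                       timepoint = c("pre", "post"),
                       layer_index = 0:5, stringsAsFactors = FALSE)
  layer$mode <- "ET"
  layer$mean_intensity <- rnorm(nrow(layer), 100, 3) +
    ifelse(layer$timepoint == "post" & layer$layer_index <= 1, 25, 0)
  rep <- analyze_study(fibre, layer, alpha = 0.05)
  # training effect on whole-fibre intensity detected, post hoc triggered
  expect_lt(anova_effect(rep$whole_fibre$mean_intensity$anova, "training")$p,
            0.05)
  expect_false(is.null(rep$whole_fibre$mean_intensity$posthoc))
  # interaction triggered within-layer t tests flagging the PM/first layers
  el <- rep$layered$ET$mean_intensity
  expect_lt(anova_effect(el$anova, "training:layer")$p, 0.05)
  wl <- el$within_layer
  expect_true(all(wl$p[wl$layer <= 1] < 0.05))
  expect_true(all(wl$p[wl$layer >= 3] > 0.05))
  # bookkeeping: every listed test has a recorded p (no orphans)
  expect_true(all(is.finite(rep$tests$p)))
})

test_that("null tables rarely trigger the within-layer cascade", {
  set.seed(401)
  n_runs <- 120
  triggered <- vapply(seq_len(n_runs), function(i) {
    layer <- expand.grid(subject_id = sprintf("s%02d", 1:8),
                         timepoint = c("pre", "post"),
                         layer_index = 0:5, stringsAsFactors = FALSE)
    layer$mode <- "ET"
    layer$mean_intensity <- rnorm(nrow(layer), 100, 3)
    fibre <- expand.grid(subject_id = sprintf("s%02d", 1:8),
                         timepoint = c("pre", "post"), stringsAsFactors = FALSE)
    fibre$mode <- "ET"; fibre$fibre_type <- "I"
    fibre$mean_intensity <- rnorm(nrow(fibre), 100, 5)
    rep <- analyze_study(fibre, layer, alpha = 0.05)
    !is.null(rep$layered$ET$mean_intensity$within_layer)
  }, logical(1))
  expect_gte(mean(!triggered), 0.9)
})
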