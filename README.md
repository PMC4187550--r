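# glut4layers

Layered quantitation of GLUT4 distribution in single muscle-fibre
immunofluorescence images.

## What this is for

GLUT4 is the insulin-responsive glucose transporter of skeletal muscle.
In fibre cross-sections it appears as large (>1 µm) clusters (trans-Golgi
network stores) and small (<1 µm) spots (endosomes and GLUT4 storage
vesicles, below confocal resolution), enriched at the fibre periphery and
around nuclei. Exercise-training studies ask where GLUT4 sits relative to
the plasma membrane (PM) and how that changes pre- to post-training.

`glut4layers` implements the full image-analysis and statistics pipeline
for that question, aimed at muscle physiologists and image analysts:

1. **Segmentation** — an active contour (snake) on the dystrophin channel
   finds the PM midline: it minimises
   `E = ∫ (α|v′|² + β|v″|²)/2 ds + E_ext(v)` with a bright-ridge external
   energy, so the converged polygon sits on the dystrophin band midline.
2. **Layers** — a PM band of halfwidth 2.5 px about the midline (5 px
   total), then twenty concentric 1 µm intracellular shells from the
   Euclidean distance map of the fibre interior.
3. **Spots** — background subtraction + high-pass enhancement, a uniform
   study-level intensity threshold, 8-connected components, equivalent
   diameter `d = 2√(area/π)`, classified large (≥1 µm) / small (<1 µm),
   and assigned to layers by centroid.
4. **Metrics** — whole-fibre mean raw GLUT4 intensity, per-class spot
   counts/densities/areas, mean spot size = total area / count, per-layer
   intensity and large-spot density.
5. **Statistics** — training × mode mixed repeated-measures ANOVA for
   whole-fibre metrics, training × layer within-subject ANOVA for layered
   metrics, Bonferroni post hoc on significant main effects, and
   within-layer paired t tests when the training × layer interaction is
   significant.

A synthetic image generator (`generate_fibre_geometry()`, `plant_spots()`,
`render_image()`, `generate_study()`) produces multi-channel fibre images
with exact ground truth, so the entire pipeline is testable without
microscope data. Its defaults mirror the study design it emulates:
8 subjects per training arm, 3 replicate sections × 5 fibres per type per
timepoint (30 images per subject per timepoint), and training effects of
+15% whole-fibre intensity, +30% large-spot count, +10% large-spot size,
+17% small-spot size.

## Worked example

```r
library(glut4layers)

# a small synthetic training arm with the default planted effects
cfg_study <- synth_study_config(
  n_subjects_per_mode = 4, modes = "ET",
  fibres_per_section_per_type = 2, replicates = 1,
  radius_um_range = c(12, 15), pixel_size = 0.25, seed = 7)
generate_study(cfg_study, "demo_study")

quantify_study("demo_study", pipeline_config(n_layers = 8))
report <- run_stats("demo_study")
print(report)
#> <glut4_report> alpha = 0.05
#>   whole-fibre metrics analysed: mean_intensity, large_density,
#>     mean_large_size, small_density, mean_small_size
#>   ET/mean_intensity: training x layer p = 0.002151 -> within-layer t tests run
#>   ET/large_per_area: training x layer p = 0.1114
#>   tests run: 12

print(report$whole_fibre$mean_intensity$anova)
#> Repeated-measures ANOVA
#>     effect df     ss     ms     f       p          stratum
#>  Residuals  3  65809  21936    NA      NA          subject
#>   training  1 194295 194295 29.23 0.01241 subject:training
#>  Residuals  3  19939   6646    NA      NA subject:training
```

The whole-fibre GLUT4 intensity shows a training main effect
(p = 0.012: the generator planted a +15% post-training increase), and the
training × layer interaction for layer intensity is significant
(p = 0.0021), triggering the within-layer paired t tests that localise the
increase to the PM-adjacent layers. `demo_study/` now contains
`fibre_metrics.csv`, `layer_metrics.csv`, `spots.csv`, `qc.csv` and
`report.json`/`report.txt`.

A command-line front end with the same stages ships in
`inst/scripts/glut4-pipeline.R` (subcommands `simulate`, `quantify`,
`stats`; exit codes 0 success / 1 validation / 2 runtime / 3 QC).

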