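---
title: "Methods: layered quantitation of GLUT4 in muscle fibre images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layered quantitation of GLUT4 in muscle fibre images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

GLUT4 is the insulin-responsive glucose transporter of skeletal muscle. In
cross-sections of single fibres it appears as large (>1 µm) clusters —
attributed to trans-Golgi network stores — and small (<1 µm) spots that
subsume endosomal stores and GLUT4 storage vesicles below confocal
resolution, superimposed on a diffuse background. The biological questions
this package serves are *where* GLUT4 sits relative to the plasma membrane
(PM) and *how* that distribution changes with exercise training. Answering
them requires: finding the PM midline in a dystrophin-stained channel,
slicing the fibre interior into concentric 1 µm shells, counting and sizing
GLUT4 spots per shell, and running within-subject statistics across
pre/post-training timepoints and training modes (endurance, ET, versus
sprint interval training, SIT).

`glut4layers` implements that pipeline end to end, plus a synthetic image
generator with exact ground truth so every stage is testable without
microscope data.

## Fibre segmentation: the snake

The PM midline is recovered with a classical active contour (snake): a
closed polygon `v(s)` minimising

    E = ∫ (α |v'|² + β |v''|²) / 2 ds + E_ext(v)

with tension `α`, rigidity `β`, and an external energy built from the
smoothed dystrophin channel. Two external functionals are supported:

* a **bright-line (ridge) term**, `E_line = −(G_σ ∗ I)` — the default; and
* the **edge term**, `E_edge = −|∇(G_σ ∗ I)|²`, blendable via
  `snake_edge_weight`.

The line term is the default because the dystrophin signal is a *band*
roughly 5 px wide: its gradient magnitude peaks on the two flanks of the
band and vanishes on the midline, so a pure edge functional equilibrates
2–3 px off the midline. The smoothed-intensity maximum, by symmetry, sits
exactly on the midline, which is the landmark the layer geometry is
anchored to. On a noiseless synthetic ring the converged contour sits within
0.05 px (mean radial error) of the true midline; under heavy noise
(signal-to-noise 5) it stays within 1.5 px.

Numerics: the internal energy is discretised with circulant second/fourth
difference operators and updated semi-implicitly (internal forces implicit
through a precomputed matrix inverse, external forces explicit), with the
contour resampled to uniform arc length every iteration. Evolution stops
when the largest vertex displacement in one iteration falls below
`snake_tol_px` (default 0.05 px) or at `snake_max_iter` (2000). The
defaults `α = 0.05`, `β = 2`, `σ = 2 px`, step `0.5`, external weight `4`
are fixture-stable choices — the imaging literature this design follows
does not prescribe them — and all are exposed in the configuration.
Initialisation is automatic: Otsu threshold of the dystrophin channel,
largest connected object, filled, boundary dilated outward by 3 px. Only
the largest object is analysed (one fibre per image); a blank or too-small
channel raises a segmentation failure that the batch driver converts into a
QC record.

## PM band and concentric layers

The Methods this package reimplements describe the dystrophin-covering
region both as "2.5 pixel thick" and as a "5 pixel PM layer"; the two are
reconciled as a band of **halfwidth 2.5 px about the midline** (total
thickness 5 px). The band holds every pixel whose centre lies within the
halfwidth of the contour polyline, computed from exact point-to-segment
distances (a Euclidean distance transform only pre-selects candidates).

Layers are built from the Euclidean distance map of the intracellular mask:
depth of a pixel = distance to the nearest non-intracellular pixel centre,
i.e. depth is measured **from the inner edge of the PM band**, not the
midline — so "layer 1" is the first fully intracellular 1 µm shell,
distinct from the PM layer, matching how the PM and 1 µm bars are reported
separately. Layer `k` holds pixels with `(k−1)·t < d ≤ k·t` (half-open,
boundary assigned inward — a deterministic convention, stated because the
source is silent); deeper pixels form the core. Twenty layers are emitted
by default; layers that do not fully enclose the deeper interior (irregular
or small fibres) carry `complete_flag = FALSE` rather than being dropped.
The Euclidean (not chamfer) transform is used because 1 µm shells at
~0.2 µm/px sampling are only ~5 px thick and chamfer bias would be a
noticeable fraction of that.

## Spot detection and classification

Detection (never intensity measurement) runs on a filtered copy of the
GLUT4 channel:

1. *No-neighbour background subtraction*: `F1 = max(I − w·G_σb(I), 0)` with
   `σb = 10 px`, `w = 0.9`. This emulates a single-plane out-of-focus light
   subtraction; the original implementation is proprietary, so this stage
   is declared an approximation with the same intent and interface.
2. *High-pass ("HiGauss") enhancement*: `F2 = max(F1 + g·(F1 − G_σh(F1)), 0)`
   with `σh = 2 px`, gain `g = 2`.

Spots are the 8-connected components of `F2 ≥ threshold` within the fibre
region, minus components smaller than `spot_min_area_px` (default 4 px,
suppressing single-pixel noise; the source states a size threshold existed
but not its value). The intensity threshold is a **study-level constant**
(uniform across all images compared), default 4500 a.u. on the filtered
scale — roughly half the filtered amplitude of a rendered spot, the value
at which planted diameters are recovered most faithfully on the synthetic
fixture. Each component's equivalent diameter is `2·√(area/π)`; spots at or
above 1 µm are `large`, below are `small` (the measure-zero boundary case
is assigned to large as a documented tie-break). Spots are detected once
over the whole fibre and assigned to layers by their intensity-weighted
centroid — re-detecting within each layer mask would artificially split
spots straddling shell boundaries. Two true spots merged by the PSF into
one component are counted as one spot; no splitting is attempted.

## Metrics

Whole-fibre GLUT4 intensity is the arithmetic mean of the **raw** channel
over the intracellular mask — no preprocessing touches intensity
quantitation, and the filtered matrix carries a class tag that the
intensity functions reject, so the separation is enforced by construction.
Per fibre and size class the package reports count, count per µm² of fibre
area, total spot area, and mean spot size = total area / count (`NA`, not
zero, for an empty class). Per layer it reports mean raw intensity and
large-spot count per layer area. Fibre-level records are always retained;
aggregation for statistics is fibre → subject × timepoint (× fibre type)
means. Whether the original analysis averaged per-section before
per-subject is not stated; the fibre → subject order is this package's
documented choice.

## Statistics

The inferential cascade mirrors the study protocol exactly:

* whole-fibre metrics: mixed repeated-measures ANOVA, training (within) ×
  mode (between), via `aov` with `Error(subject/training)`; significant
  main effects get Bonferroni pairwise comparisons;
* layered metrics (fibre types pooled, as in the source): per training
  mode, a two-within ANOVA, training × layer, with
  `Error(subject/(training×layer))`; a significant layer main effect
  triggers Bonferroni pairwise layer comparisons; a significant
  training × layer interaction triggers **unadjusted** within-layer paired
  t tests (the protocol applies Bonferroni only to main-effect pairwise
  comparisons; a flag can change this);
* α = 0.05 throughout; no sphericity correction by default (none is
  mentioned in the protocol this follows).

The paired t is computed from the closed form so that identical pre/post
vectors return `t = 0, p = 1` ("no evidence of change") instead of erroring.
Designs with missing cells or unequal group sizes are rejected outright —
no imputation. The ANOVA implementation is cross-checked in the test suite
against an independent hand-written balanced cell-means decomposition, and
its operating characteristics are verified by simulation: type-I error of
the training test within [0.03, 0.07] at α = 0.05, and ≥80% power for a
planted effect of 1 SD. Planted effects in these simulations are expressed
as Cohen's *d_z* — relative to the standard deviation of the
*within-subject change* — the standard effect-size scale for paired
designs. Both power simulations use the same 16-subject cohort (8 per mode
in the mixed design). For orientation: the training main effect at
*d_z* = 1 has ~97% power there, while the training × layer interaction
with the effect confined to the PM-adjacent layers has ~94% power at 16
subjects but only ~60% in a single 8-subject arm — layer-localised
conclusions from one arm need strong effects, as reflected in the shipped
checks.

## The synthetic generator

`generate_fibre_geometry()` builds a star-shaped fibre (radius modulated by
a band-limited random harmonic series), 3–8 peripheral nuclei, and a
rasterised interior. `plant_spots()` places exact numbers of large and
small spots with rejection sampling: diameters within 0.05 µm of the 1 µm
boundary are resampled (no ambiguous ground truth), overlapping placements
(centre distance below the sum of radii) are rejected so the planted count
equals the detectable count, and configurable fractions are peripheral
(depth ≤ 1 µm from the PM midline) or perinuclear (within 2 µm of a nuclear
boundary). `render_image()` draws spots as uniform disks — the simplest
model whose post-PSF equivalent diameter is controllable — over a diffuse
interior background with a peripheral exponential enrichment
(`1 + g·exp(−depth/1 µm)`), a bright dystrophin band on the midline, a
bimodal MHCI channel (type I high, type II low) and DAPI nuclei, convolves
with a Gaussian PSF and adds Gaussian (optionally Poisson) noise.

`generate_study()` reproduces the sampling design: per subject and
timepoint, 3 replicate sections × 5 fibres per type × 2 types = 30 images;
8 subjects per training mode. Post-training ground truths scale by the
configured effect sizes, whose defaults are the training responses the
method is meant to resolve: +15% whole-fibre intensity, +30% large-spot
count, +10% large-spot mean size, +17% small-spot mean size, no change in
small-spot count. Size effects apply to mean spot *area*, so sampled
diameters scale by `√(1+e)`. Spot counts are Poisson draws, subject and
fibre heterogeneity are lognormal factors (CV 8% and 6%), and the
peripheral intensity gradient — for which no quantitative basal profile is
published — is a free parameter fixed at 0.8 (pre) with a +25% default
training response. Determinism is strict: one master seed, per-image seeds
derived by stable hashing of (subject, timepoint, replicate, fibre), and
identical seeds give bit-identical ground truth and noise-free renders.

What the generator does *not* emulate — and hence what green tests do not
certify on real data: longitudinal sections and T-tubule striations,
photobleaching, chromatic shift, uneven illumination, section folds,
multi-fibre fields, and hybrid (I/IIa) fibres. Cross-image intensity
comparability is assumed, as it is in the source design where pre/post
sections share a slide.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline at reduced
imaging scale — fibre radii 12–15 µm at 0.25 µm/px (images ≈ 150 px), 6–8
subjects, one replicate section of 3 fibres per type, 8 layers — which
keeps whole-study runs to a few minutes while preserving every structural
property of the full-scale design (the sampling-plan checks use the full
3 × 5 × 2 design with rendering disabled). Statistical simulations run on
subject-level tables directly: 2000 null tables for the type-I check, 500
for each power check.

## Known limitations

* The snake assumes one dominant, roughly star-shaped fibre; concave necks
  deeper than the smoothing scale may be bridged.
* Merged spots are not split; large-spot counts are slightly conservative
  and mean sizes slightly inflated in crowded peripheries.
* The no-neighbour emulation approximates a proprietary algorithm; its
  parameters are declared approximations, not recovered constants.
* The numeric detection threshold used in the original study is
  unpublished; the default here is calibrated on the synthetic fixture and
  must be re-tuned for real acquisitions (it is a config value, uniform
  per study by design).
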