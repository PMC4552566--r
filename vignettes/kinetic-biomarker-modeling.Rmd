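---
title: "Modeling kinetic patterns of exercise metabolomics time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling kinetic patterns of exercise metabolomics time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metakin)
library(dplyr)
```

## The data model and its assumptions

`metakin` analyzes tidy longitudinal concentration tables from incremental
cycle-ergometry cohorts: one row per subject × metabolite × sampling
stage, with stages `rest`, `level_1 … level_K` (workload 50 + 25·(k − 1) W)
and `recovery`. The pipeline's central assumptions are:

* **Alignment by relative workload.** Subjects differ in maximum workload
  (150–425 W), so absolute time is not comparable. Every sample is mapped
  to 100·W/W~max~ percent of the individual maximum; rest is 0, recovery
  sits at 117 (the cohort median of 100·t~recovery~/t~max~ when time
  stamps exist, available via `median_recovery_position()`). Because the
  protocol increments workload uniformly in time, workload-proportional
  and time-proportional mappings coincide up to the skipped 25 W step;
  we use the workload-proportional one because the clustered axis is a
  relative *workload* axis. The alternative is equivalent for
  protocol-conformant cohorts.
* **Medians as the cohort summary.** All downstream statistics operate on
  pointwise median curves across subjects, which makes the pipeline
  indifferent to single aberrant subjects without any outlier-detection
  machinery. The three documented manual exclusions
  (`default_exclusions()`) blank known artifact cells before analysis.
* **Linear interpolation, no extrapolation.** Gaps between samples —
  including a missing maximum-load sample, the most common real-world
  defect — are bridged by a single linear segment. Outside a subject's
  first/last observed sample the subject simply contributes nothing to
  the median.

## Biomarker ranking

The directional maximum fold change of a median curve is
`conc_max / conc_min` when the minimum occurs first and
`conc_min / conc_max` otherwise, so decreasing metabolites yield MFC < 1.
Per-subject interpolated values at the two extremum *positions* provide
paired samples for a two-sided Wilcoxon signed-rank test. Two details
matter:

* **Exact null distribution.** With no ties among the absolute
  differences the exact signed-rank distribution is used at any n (47
  complete pairs in a typical cohort). This is why the smallest attainable
  two-sided P values are lattice values like 4/2^47 ≈ 2.8e-14, and why
  metabolites with equally extreme rank patterns share identical P —
  ranks, not magnitudes, enter the statistic. Ties fall back to the
  normal approximation with continuity correction; zero differences are
  dropped (the classic treatment). The branch taken is reported per
  metabolite.
* **FDR control.** Raw P values are Benjamini–Hochberg adjusted across
  the panel (m = panel size). Predictor classes apply to the *magnitude*
  max(MFC, 1/MFC) — moderate > 1.20, strong > 1.40, both at adjusted
  P < 0.001 — so a metabolite falling to 0.70 is judged like one rising
  to 1.43. The published thresholds were drawn only on the increasing
  side; extending them symmetrically is this package's interpretation,
  and with the default panels it changes no label.

A Shapiro–Wilk screen (α = 0.01) of the samples at both extrema is
computed for reporting only; the pipeline always tests nonparametrically
so that all metabolites are compared on the same scale.

## Kinetic signatures and their classification

Median curves are smoothed by ordinary least squares with a degree-9
polynomial. Degree nine is the default because it is the lowest degree
that tracks every template shape in the package's library — including
the recovery-phase hockey stick — without visible lag, while higher
degrees begin to chase interpolation kinks; it remains a parameter
(`degree`) and the residual sum of squares is reported per fit so users
can pick a degree by inspection. Numerical choices:

* The abscissa is linearly mapped to [0, 1] before building the
  Vandermonde matrix; a raw degree-9 basis on 0–117 has condition number
  around 10^18 and fails outright. Coefficients are reported on the
  normalized axis. The QR-based fit reproduces any generating polynomial
  of degree ≤ 9 on the 118-point grid to ~1e-12 relative error.
* Fits are converted to relative curves 100·(f(s) − f(0))/f(0). This is
  exactly 0 at rest, scale-free, and the unit in which curves are
  clustered and displayed. A fit with f(0) ≤ 0 is rejected as
  nonphysical.
* Polynomial smoothing leaves ringing artifacts of roughly 3 % near
  support edges and sharp kinks; the package reports, but does not
  correct, them.

Response patterns are labeled by `classify_kinetic_pattern()`. A curve
whose total relative range stays below 20 percentage points — twice the
±10 % band accepted as biological/analytical variability — is
**sustained**. Otherwise the axis is partitioned at 25/75/100 and each
segment (early, halving, late, delayed ≡ recovery) is scored by its
excursion per unit position. The label then follows the taxonomy's
semantics rather than a bare argmax:

1. **delayed** if the recovery segment scores at least as high as every
   exercise segment;
2. **late** if the final exercise quarter still accumulates change at no
   less than half the best exercise segment's rate — a late response is
   one that is *still changing* at the end of exercise, whereas early and
   halving responses have plateaued;
3. otherwise **early** or **halving** by direct comparison.

The argmax rule is fragile for the most important boundary case, a
uniform ramp, whose early/halving/late scores tie exactly; any noise or
smoothing then decides the label arbitrarily. The decision list above
classifies all seven noiseless template shapes correctly and keeps mean
recovery above 95 % at 5 % measurement noise. The segment boundaries,
the sustained band and the late ratio (0.5) are exposed as arguments.

`match_template()` offers the alternative basis-function route — least
squares amplitude fits of the template library — retained for diagnosis;
a non-flat shape must reach a fitted amplitude of 10 % (the variability
band) to beat the flat template, otherwise projection onto any shape
would trivially reduce the residual of pure noise.

## Clustering and shape templates

Signatures are clustered on their **relative** (%) curves with Euclidean
distance and complete linkage, and the tree is cut at height 35. On
absolute concentrations a single high-abundance analyte (glucose, mM
scale against µM amino acids) would dominate every distance regardless
of shape, and a cut height of 35 is only meaningful in percent units;
`mode = "absolute"` and `"row_scaled"` remain available for sensitivity
analysis, as do `linkage` and `cut_height`. Cluster ids are renumbered by
first appearance along the dendrogram leaf order, which makes
assignments deterministic and invariant to metabolite input order (up to
renaming). Each cluster's pointwise median relative curve is its kinetic
shape template, labeled with the same pattern classifier. The row-scaled
heatmap matrix (`heatmap_export()`) is display-only and never feeds back
into clustering.

The number of clusters a real cohort yields at height 35 depends on the
distance/linkage conventions, which the original analysis did not record;
cluster count should therefore be treated as a soft, convention-dependent
quantity, while the *membership structure* (which metabolites travel
together) is stable.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` reproduces the protocol's structure: 47 subjects
(group sizes 16/8/11/12 across male/female × average/athletic), maximum
workloads uniform on {150, 175, …, 425} W, profiling samples at 2:30 min
into each level, recovery 5 min after exercise end, and a
12/47 probability that the maximum-load sample is missing. Concentrations
follow `baseline · (1 + template(s)) · ε` with ε log-normal, mean 1, CV
`noise_cv` (default 0.1 — the original study reports no noise figure, so
this is a pragmatic assay-level choice). Template curves live directly on
the relative-position axis, so ground truth is exactly comparable to
pipeline output after rescaling. The logarithmic shape is anchored as
ln(1 + βs)/ln(1 + 100β) (β = 0.2) because a bare logarithm is undefined
at rest; the sigmoid is centred at s = 50 with τ = 8; the hockey stick is
piecewise linear with a free breakpoint (our definition — the shape is
conventionally described but not parameterized in the exercise
literature).

The default 30-metabolite panel calibrates shapes and amplitudes to the
published kinetic behavior of the corresponding analytes (acetylcarnitine
+67 % late with a −10 % early dip, valerylcarnitine's −16 % early
transient, methionine's +13 % sigmoid, a glucose hockey stick with a
25-point total swing so that it clears the sustained band, and a majority
of sustained channels). Two honest gaps between simulation and reality:

* **Transient dips narrower than the sampling interval are attenuated.**
  The early dip peaks at s ≈ 12.5, but a 150 W subject's first exercise
  sample sits at s = 33; linear interpolation cannot recover what was
  never sampled, so estimated fold changes for dip metabolites run a few
  percent below the continuous-curve truth. This is a property of the
  protocol, not of the code — the same attenuation affects real cohorts.
* **No physiological covariance.** Noise is independent across samples
  and metabolites; there is no heart-rate/VO₂ modeling, no training-state
  effect, and per-subject baseline spread is off by default
  (`baseline_cv` adds log-normal between-subject abundance variation for
  sensitivity studies; because the pipeline normalizes *after* taking
  cohort medians, strong baseline spread directly inflates median-curve
  noise — a useful stress test, but not part of the reference noise
  model). Passing recovery tests on this generator therefore demonstrates
  correctness of the pipeline's mechanics, not robustness to every
  biological confounder.

The lactate channel is a deterministic exertion profile (1.2 mM rest,
8.5 mM maximum, 7.2 mM recovery medians; cubic rise, linear washout)
sampled at 1:30 min into each level, 60 s before the profiling sample.

## Problem sizes used by the test suite

The suite exercises the pipeline at the study's own scale: 47-subject
cohorts on the 118-point grid, a 7-metabolite one-shape-per-kind panel
for recovery checks (noise-free, and 20 seeded cohorts at 5 % noise with
the observed missing-maximum rate), the 30-metabolite default panel for
end-to-end classification, 10 000 random curves against a brute-force
fold-change oracle, full 2^n enumeration of the signed-rank null up to
n = 10, and 50 random vectors against an independent step-up FDR
implementation.

## Known limitations

* The extremum positions are taken from the median curve and reused for
  every subject; metabolites whose individual extrema shift widely
  between subjects lose power relative to subject-specific extraction.
* The pattern classifier is a deliberate operationalization of a verbal
  taxonomy; curves near segment boundaries (e.g. a sigmoid centred at 70)
  are genuinely ambiguous and the configurable boundaries matter there.
* Fold changes carry no confidence intervals; ranking significance rests
  entirely on the paired signed-rank test at the extrema.
* Reproducing a published cluster count requires the original
  distance/linkage conventions, which are not recoverable from the
  published record (see above).
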