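# metakin

Kinetic pattern modeling and dynamic biomarker ranking for longitudinal
targeted-metabolomics data from incremental exercise (cycle-ergometry)
studies.

## The problem

In an incremental exercise test, subjects cycle from 50 W in 25 W / 3 min
steps up to their individual maximum workload, with blood sampled at rest,
at every workload level, and five minutes into recovery. Because maximum
workload differs between subjects (150–425 W), the resulting per-subject
metabolite concentration time courses have different lengths and cannot be
compared directly. `metakin` implements a complete analysis pipeline for
such cohorts, aimed at physiologists and clinical bioinformaticians who
want to rank *dynamic* biomarker candidates — metabolites whose
concentration kinetics, not just endpoint values, respond to exertion —
and to characterize the *shape* of that response.

## The method

1. **Alignment.** Each subject's trajectory is rescaled to a common
   relative-workload axis: rest = 0 %, individual maximum = 100 %,
   recovery = 117 % (the cohort median relative recovery time). Curves are
   completed by linear interpolation on a unit grid (118 points) with no
   extrapolation beyond a subject's observed support; the cohort **median
   curve** per metabolite is the outlier-robust summary.
2. **Ranking.** For each median curve the *directional maximum fold
   change* is computed from its extrema:

   ```
   MFC = conc_max / conc_min   if the minimum occurs first
   MFC = conc_min / conc_max   otherwise
   ```

   Subjects' interpolated values at the two extremum positions give paired
   samples for an exact two-sided Wilcoxon signed-rank test (normal
   approximation with continuity correction only when ranks tie);
   Benjamini–Hochberg adjustment controls the FDR across the panel. A
   metabolite is a *moderate* predictor if max(MFC, 1/MFC) > 1.20 and a
   *strong* predictor if > 1.40, each at adjusted P < 0.001 (volcano-plot
   thresholds).
3. **Kinetic signatures.** A degree-9 polynomial f(x) = Σ aᵢxᵢ is fitted
   to each median curve (abscissa normalized to [0, 1] for conditioning)
   and expressed as the relative curve 100·(f(s) − f(0))/f(0), i.e. percent
   change from rest.
4. **Shape templates.** Signatures are grouped by agglomerative
   hierarchical clustering (Euclidean distance on relative curves,
   complete linkage, tree cut at height 35); each cluster's median
   relative curve is its *kinetic shape template*.
5. **Classification.** Every signature is labeled **sustained**, **early**,
   **halving**, **late** or **delayed** from the distribution of its
   excursion across the exercise/recovery axis, and combined with the
   predictor class into headlines such as `"strong predictor, late
   marker"`.

A synthetic-cohort generator (`simulate_cohort()`) reproduces the full
study protocol with known ground-truth shapes (constant, logarithmic,
sigmoid, linear/quadratic/exponential ramps, hockey stick) plus
multiplicative log-normal noise and realistic missing maximum-load
samples, so the whole pipeline is testable without clinical data. A
lactate gold-standard channel (`lactate_reference()`) is calibrated to
median 1.2 mM at rest, 8.5 mM at maximum and 7.2 mM after recovery.

## Worked example

```r
library(metakin)
library(dplyr)

sim <- simulate_cohort(n_subjects = 47, panel = default_panel(),
                       noise_cv = 0.1, p_missing_max = 12/47, seed = 1)
res <- run_pipeline(sim$cohort, exclusions = default_exclusions())
res
#> <metakin_result>
#>   metabolites: 30
#>   clusters:    12 at cut height 35
#>   candidates:  10
#> # A tibble: 10 × 4
#>    metabolite                     mfc    p_adj headline
#>  1 acetylcarnitine_C2            1.72 1.71e-13 strong predictor, late marker
#>  2 propionylcarnitine_C3         1.59 1.71e-13 strong predictor, late marker
#>  3 alanine                       1.44 2.84e-13 strong predictor, late marker
#>  4 arginine                      1.35 1.71e-13 moderate predictor, late marker
#>  5 butyrylcarnitine_C4           1.32 3.65e-13 moderate predictor, late marker
#>  ...
```

The headline table is the pipeline's final product: acetylcarnitine-like
metabolites (β-oxidation end products) emerge as strong late markers — the
concentration accelerates toward the end of exercise with a maximum fold
change of 1.72 between the median-curve extrema, at an FDR-adjusted
signed-rank P of 1.7e-13 across 47 paired subjects — while glucose-like
channels classify as delayed markers (hockey-stick overshoot during
recovery). `tidy(res)` returns the full 30-row classification,
`glance(res)` a one-row run summary, and `plot_volcano(res$biomarkers)`,
`autoplot(res$signatures)`, `autoplot(res$clusters$templates)` and
`plot_signature_heatmap(res)` draw the standard figures. Intermediate
stages are ordinary tibbles (`rescale_cohort()`, `interpolate_cohort()`,
`extract_median_curves()`, `biomarker_table()`, …), so each step can be
piped, inspected and exported with `write_table()`.

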