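---
title: "Plasma thermogram analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plasma thermogram analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlbkit)
```

Thermal liquid biopsy records the excess specific heat capacity
$C_p^{ex}(T)$ of a dilute blood-plasma sample during a controlled
temperature scan. The bulk plasma proteome denatures in overlapping
transitions, so the curve shape is a composite fingerprint of plasma
composition. This vignette documents how the package models that signal,
the tunable parameters and their defaults, and the choices made where more
than one reasonable design existed.

## The preprocessing chain

A raw DSC scan is a (temperature, heat-signal) table. Finalizing it into a
thermogram applies four steps, in order:

1. **Buffer subtraction.** The matched buffer reference scan is linearly
   interpolated onto the sample's temperatures and subtracted pointwise.
   At 0.1 °C-scale sampling the curves are locally linear, so higher-order
   interpolation would change values by far less than instrument noise;
   linear interpolation is used everywhere in the package for that reason.
2. **Concentration normalization.** The signal is divided by
   (scan rate × protein concentration × cell volume), converting a
   power-like instrument signal into heat capacity per gram of protein.
   Defaults: cell volume 0.3 ml (the instrument's thermal sensing volume)
   and scan rate 1 °C/min; all three factors are arguments. Whether one
   normalizes by concentration alone or by total protein mass in the
   sensing volume is a convention choice — both are pure rescalings, and
   every downstream temperature-, ratio- and shape-based quantity is
   invariant to it. We expose the full product so either convention is a
   parameter setting.
3. **Linear baseline correction.** Plasma thermograms sit on a gently
   sloping residual baseline. We fit the straight line through the
   (mean T, mean signal) points of two anchor windows and subtract it;
   after correction the anchor-window means are zero by construction. The
   default anchors 45–50 °C and 85–90 °C are the flat flanks outside all
   three transition windows; both are configurable for instruments with a
   different quiet range. Each anchor must contain at least three points.
4. **Regridding.** Linear interpolation onto the uniform 45.0–90.0 °C grid
   with 0.1 °C steps (451 points, `tlb_grid()`). The operation is
   idempotent and preserves values at coinciding points.

Duplicate scans are combined by pointwise mean; the maximum pointwise
spread between replicates is recorded in the provenance rather than
thresholded, because an accept/reject rule for replicate agreement is a
laboratory policy, not a property of the data.

Negative $C_p^{ex}$ values after correction are retained. Slight negative
excursions are a normal artifact of baseline removal, and clipping would
bias the area and first-moment statistics.

## The 19-metric panel

Peak detection uses fixed windows rather than derivative-based peak
finding: the maximum amplitude within 60–66 °C (Peak 1), 67–73 °C
(Peak 2) and 73–81 °C (Peak 3). Fixed windows make the metrics comparable
across samples whose transitions shift by a degree or two, which is the
biological signal of interest. Three conventions needed fixing:

* **Shared boundaries.** The printed window ranges meet at 73 °C. Windows
  are half-open, $[low, high)$, so each grid point belongs to at most one
  window and results are deterministic; the 66–67 °C gap belongs to no
  peak window.
* **Ties.** All extremum searches break ties toward the lowest
  temperature, so plateaus give reproducible positions.
* **Valley.** V1.2 is the minimum strictly between the *detected* Peak 1
  and Peak 2 positions, not between fixed window edges.

The global metrics are: the profile maximum and its temperature over the
full grid; the **first-moment temperature**
$T_{FM} = \sum_i T_i\,C_{p,i} \big/ \sum_i C_{p,i}$, the amplitude-weighted
mean temperature (the standard single-number summary of a thermal-stability
shift — if the total signal is not positive it is undefined and returned as
`NaN`); the trapezoidal **area** over 45–90 °C; and the **width at half
height**, the span between the first upward and last downward crossings of
half the global maximum, located by linear interpolation between bracketing
grid points. For multi-peak envelopes the outermost crossings are the
conventional reading of "width at half height"; if the curve never falls
below half height on one side, the width is truncated at the grid edge and
flagged with a warning. Ratios with a zero denominator are returned as
`NaN` with a warning rather than aborting the panel.

On an analytic Gaussian these definitions have closed forms
(width $= 2\sigma\sqrt{2\ln 2}$, area $= A\sigma\sqrt{2\pi}$), which the
test suite checks, alongside a brute-force oracle evaluated on a 0.001 °C
grid. The grid discretization bounds the achievable agreement: an extremum
position on the 0.1 °C grid can sit up to one step from the analytic one,
and amplitudes are exact to about $A\Delta^2/(2\sigma^2) \approx 10^{-3}A$
for the narrowest transitions.

## The synthetic cohort generator

The study's patient data are not publicly available, so the package ships
a generator that emulates the *structure* the analysis consumes. Each
phenotype template is a mixture of three Gaussian components (center,
width, amplitude) in two states — acute and quiescent — blended by a
recovery fraction $\lambda$ that runs from 0 at baseline (T0) to 1 at
follow-up (Tfu). Gaussians were chosen over thermodynamic two-state
transition models because the analysis consumes only curve shape, and
Gaussians give closed-form oracles for every metric.

The default templates encode the qualitative signatures: a quiescent curve
with a dominant ~63 °C component, a smaller ~70 °C component and a small
~77 °C shoulder; acute TMI with a strongly diminished Peak 1 and elevated
shoulder; acute nTMi with a diminished Peak 1 and an elevated 68–75 °C
region; and a TMI subtype with a dominant, well-defined 80 °C component.
Recovery fractions over (T0, T2, T4, T24, T48, Tfu) rise monotonically and
faster for nTMi (0, 0.10, 0.25, 0.55, 0.75, 1) than for TMI
(0, 0.05, 0.12, 0.35, 0.55, 1); cCAD is stable, with an acute curve only
slightly below its quiescent one. **All template constants are package
defaults chosen for qualitative realism and separability, not measured
values**; no claim is made that they match any cohort's biology
quantitatively.

Noise has three levels, all defaults chosen to be small relative to the
~0.3 cal/°C·g major transition, as in well-run DSC practice:
per-point additive noise (SD 0.004 cal/°C·g, instrument-like),
a per-sample log-normal amplitude factor (CV 6%, concentration-assay
error), and a per-sample temperature jitter (SD 0.25 °C). Patients get one
shared amplitude factor (CV 8%) and one shared temperature offset
(SD 0.3 °C) across their timepoints, reflecting a design in which patients
serve as their own controls. The default cohort is 35 cCAD / 60 TMI /
20 nTMi patients at six timepoints, with `round(7/60 × n_TMI)` TMI
patients carrying the 80 °C subtype — a fixed count rather than a binomial
draw, so the default cohort composition is reproducible exactly.

What the generator does **not** emulate: real inter-protein correlation
structure, skewed or multi-modal biological variability, batch and dialysis
effects, or any quantitative effect size. Passing tests on synthetic data
therefore demonstrate that the pipeline's operations are correct and
calibrated, not that the package would reproduce any particular clinical
result.

## Statistical choices

* **Kruskal–Wallis per metric** (tie-corrected, $\chi^2$ reference with
  groups − 1 degrees of freedom) across phenotype groups, with family-wise
  adjustment over the 19 metrics, applied separately within each family
  (T0, Tfu, ΔTfu−T0). The default adjustment is **Holm**: it dominates
  Bonferroni uniformly, requires no independence assumptions, and — unlike
  a constant multiplier — produces adjusted/unadjusted ratios that vary by
  rank, which matches how published tables of this kind behave.
  Bonferroni and Benjamini–Hochberg are selectable.
* **Pairwise comparisons.** Between independent groups the correct
  Wilcoxon form is the rank-sum (Mann–Whitney) test; the signed-rank form
  applies to paired, within-patient data and is selected with
  `paired = TRUE` (matched by patient id). Exact null distributions are
  used for $n \le 25$ without ties, otherwise the normal approximation
  with continuity and tie correction. A metric constant across samples, or
  all-zero paired differences, yields $p = 1$ with a warning rather than
  an error.
* **Profile summaries** use the pointwise median and pointwise 2.5%/97.5%
  quantiles (linear interpolation between order statistics, R's default
  type-7 convention). Significance is assessed at the fixed 5% level.

## Clustering choices

Baseline profiles are clustered as raw 451-dimensional vectors with
Euclidean distance and **no per-feature standardization**: all grid points
share one physical unit, and standardizing would inflate the flat,
noise-dominated flanks relative to the informative peaks. Lloyd iterations
run from k-means++ seedings, keeping the best of 50 restarts by
within-cluster sum of squares; the restart envelope makes the reported
optimum stable and the within-SS non-increasing in k in practice. Clusters
are relabeled in decreasing size order so reports are deterministic, and
purity percentages are rounded half-away-from-zero to one decimal, the
convention used in printed contingency tables. Cluster-count selection
reports both the within-SS elbow and the mean silhouette, with the
silhouette maximizer recorded.

## Pipeline and reporting

`run_pipeline()` executes simulation (or file input) → censoring →
metric panels → the three statistical families → baseline clustering →
profile summaries, writing each stage as plain CSV/JSON plus a run log with
seed and parameters; identical configurations produce byte-identical
numeric outputs. The censoring rule marks post-baseline acute samples
(T2–T48) of flagged cCAD patients as excluded while keeping T0 and Tfu,
and censored samples appear in no downstream output. Cohort summary tables
compute percentages over non-missing denominators and report missing
counts alongside, so partially observed variables stay interpretable.

## Problem sizes and numerical tolerances in the test suite

The shipped tests exercise: metric agreement against a 0.001 °C
brute-force oracle on 100 random three-Gaussian profiles; scale and shift
equivariance on 200 profiles; Kruskal–Wallis type-I calibration with 1,000
null replicates at n = 20 per group (expected rejection rate within
[0.035, 0.065] at α = 0.05); exact rank-sum enumeration on two groups of
three; clustering recovery on the default 115-patient cohort; and
byte-identical pipeline re-runs. Equivariance properties are asserted on
profiles whose window maxima are interior local maxima: when a
neighbouring transition's tail dominates a window's edge, the "peak" is
pinned to the boundary and position equivariance cannot hold — a property
of the windowed-metric definition itself, not of the implementation.

## Known limitations

* Fixed peak windows misread profiles whose transitions drift outside the
  canonical ranges (e.g. a Peak 1 above 66 °C would be attributed to the
  gap or to Peak 2).
* The 19 metrics summarize curve shape; they do not deconvolve individual
  protein transitions or estimate thermodynamic parameters.
* The synthetic generator supports correctness and calibration claims
  only; effect sizes, variances and cluster separations in real cohorts
  will differ.
* k-means with Euclidean distance prefers compact, similar-scale clusters;
  strongly unbalanced or elongated cluster structure in real data may
  require other methods.
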