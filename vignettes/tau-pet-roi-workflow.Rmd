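---
title: "Cross-tracer tau-PET ROI analysis: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tracer tau-PET ROI analysis: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauroi)
```

## The problem

Tau-PET tracers (flortaucipir, RO948, MK6240) quantify neurofibrillary tau
pathology as standardized uptake value ratios (SUVR) over a cortical
parcellation. For differential diagnosis — separating Alzheimer's disease
(AD) dementia from cognitively unimpaired (CU) individuals and from non-AD
neurodegenerative disorders — regional SUVRs are pooled into composite
target regions of interest (ROIs), either *theory-driven* (following the
Braak staging of tau spread) or *data-driven* (learned from the data). Two
practical questions drive this package: can the **same** target ROI be used
across tracers, and does a **common SUVR cut-off** (around 1.35 for the
temporal meta-ROI) classify tau positivity consistently across tracers?

The package implements the full analysis chain on tabular SUVR data: a
synthetic multi-tracer cohort generator, composite ROI aggregation,
data-driven ROI selection, ROC/Youden/DeLong diagnostics, and a per-tracer
report with a cross-tracer cut-off summary.

## The synthetic cohort model

No subject-level data are distributed, so every downstream stage is
exercised on synthetic cohorts with the statistical structure the analysis
assumes. The generator uses a latent single-severity model:

* each subject draws a latent tau-burden severity $z$ from its group and
  amyloid stratum, $z \sim N(\mu, s^2)$;
* each atlas region $r$ belongs to a stage class $c(r)$ (`I_II` entorhinal,
  `III_IV` limbic/temporal, `V_VI` neocortical, `off_target`) with onset
  $\theta_c$, ordered $\theta_{I/II} \le \theta_{III/IV} \le \theta_{V/VI}$;
  regional burden is the logistic dose-response
  $b_r = \mathrm{logit}^{-1}\!\left((z - \theta_{c(r)})/\tau\right)$, so early
  Braak regions saturate before late ones as severity grows;
* the tracer maps burden to SUVR affinely,
  $\mathrm{SUVR}_r = a_t + b_t\,b_r + \delta_{c(r)} + \varepsilon$ with
  $\varepsilon \sim N(0, \sigma_t^2)$, truncated below at 0.05 SUVR. The gain
  $b_t$ is the tracer's dynamic range; the per-class shifts $\delta_c$ absorb
  class-level baseline differences such as off-target binding.

This is the minimal structure that reproduces Braak-ordered group
separation; it is a modeling choice of this package, not an estimate of any
biological process. CU heterogeneity is modeled as a two-component mixture:
a fraction of CU subjects is amyloid-positive (22–43% across the tracer
presets) with a higher latent mean, because unimodal CU distributions cannot
reproduce the observed CU/AD overlap. Amyloid status is assigned by exact
counts (`round(n * fraction)` per group) rather than Bernoulli draws, so
preset cohorts match published amyloid-positive counts exactly — in
particular the sensitivity-analysis subsets (amyloid-positive PD/PDD/DLB:
26 and 31 subjects) are reproduced deterministically. Age, sex and education
are not generated; demographic comparisons are out of scope.

### Atlas

`default_atlas()` provides 31 bilateral Desikan–Killiany-style cortical
labels plus the amygdala (64 labels). Nominal volumes are round numbers of
realistic relative magnitude; they only matter through the volume weights of
composite ROIs. Stage classes: entorhinal is `I_II`; amygdala,
parahippocampal, fusiform, inferior and middle temporal are `III_IV`;
cingulate, insula, sensorimotor and pericalcarine labels are `off_target`
(regions commonly excluded from neocortical composites); the remaining 17
bilateral labels are `V_VI`.

### Calibration of the tracer presets

The three presets (`flortaucipir`, `RO948`, `MK6240`) carry the published
group sizes, clinical subtypes and amyloid-positive fractions. The latent
parameters (tracer offset/gain/noise, stage onsets, slope, per-class shifts,
group latent means/SDs) were fit once, offline, by bounded least squares on
the *analytic* group moments of the model, targeting the published
group-level means and SDs of the four theory-driven composites (12 means and
12 SDs per tracer), with the latent scale normalized to CU amyloid-negative
$z \sim N(0,1)$. The fitted values are frozen in the package; the test suite
verifies by Monte Carlo (5,000 subjects per group) that simulated group
means land within ±0.05 SUVR of every target cell. Group means are matched
to ~0.02 SUVR; SDs are approximate (worst cells off by ~0.1 SUVR), which is
acceptable because downstream acceptance checks bind only on the means,
and the AUC ordering of composites is preserved.

The published pooled "PD/PDD" groups are split into PD without dementia
(40/30 subjects for the flortaucipir-/RO948-like cohorts) and PDD (25/17),
with amyloid-positive counts allocated by subtype so both the group totals
and the PD/PDD/DLB exclusion subsets match the published numbers. The split
itself is a synthetic design choice.

### What the generator does *not* emulate

Regional noise is independent across regions given $z$; real SUVR maps have
spatially correlated noise, partial-volume effects, and meningeal spill-in.
The single latent severity cannot produce atypical (non-Braak) spatial
phenotypes, hemispheric asymmetry, or subtype-specific topographies in
non-AD groups. Consequently, passing tests demonstrate correctness of the
*pipeline machinery* under the assumed cohort structure — not that the
data-driven selection would recover the same regions on real scans.

## Composite ROI aggregation

The four theory-driven composites are bilateral: entorhinal (stage I/II);
early tau (entorhinal, inferior temporal, fusiform, parahippocampal);
temporal meta-ROI (early tau plus amygdala and middle temporal, approximating
Braak I–IV); and neocortical meta-ROI (approximating Braak V/VI). The exact
membership of published neocortical composites varies between studies; here
it defaults to all `V_VI`-class labels (all cortical labels except temporal
meta-ROI members and limbic/off-target labels) and is overridable via
`composite_roi()`. Aggregation is the volume-weighted mean by default —
standard for published meta-ROIs — using each subject's own region volumes;
an unweighted mean is available and recorded in the ROI definition. Both
hemispheres always pool into one composite.

## Data-driven ROI selection

Per tracer and contrast (AD vs CU; AD vs non-AD):

1. **Importance**: extremely randomized trees (each tree fit on all training
   data without bagging, one random split point per candidate feature) are
   trained inside 10-fold stratified cross-validation; impurity-decrease
   importances are normalized to sum to 1 per fold and averaged. Defaults:
   500 trees, $\sqrt{p}$ features per split, unlimited depth — the ensemble
   is named in the underlying approach but its hyperparameters are not, so
   standard defaults are exposed as arguments.
2. **Dendrogram**: regions are clustered by `1 - Pearson` correlation across
   subjects with average linkage, the standard choice for strongly collinear
   imaging features. Distance and linkage are configurable in principle;
   the implemented pair is the package default.
3. **Representatives**: for $k = 1..K_{max}$ the tree is cut into $k$
   clusters and the highest-importance member of each cluster is extracted
   (ties: lexicographically smallest label). Each candidate set is scored by
   the stratified 10-fold CV AUC of its unweighted mean SUVR composite. The
   final $k$ is the smallest within one standard error of the best score —
   the one-standard-error rule, chosen to favor a minimalist representation.
   How the accuracy-versus-$k$ curve picks $k$, and whether "accuracy" is a
   composite or a classifier output, are genuinely open choices; this
   package evaluates composites (mirroring the theory-driven ROIs and making
   the paired DeLong comparison well-defined) and documents the trace so
   other rules can be applied post hoc.

All outputs are invariant to subject order (rows are canonically re-sorted
internally) and reproducible given the seed.

## Diagnostics

* **AUC**: Mann–Whitney estimator (ties count 1/2); DeLong placement-value
  variance for CIs.
* **Youden cut-point**: thresholds scan the midpoints between consecutive
  distinct pooled values plus infinite sentinels; a subject is positive iff
  score > threshold (strictly); among ties in $J$ the smallest threshold is
  returned, favoring sensitivity in a screening context. Midpoint grids make
  cut-points independent of sample ordering and land between group clusters,
  which is where published cut-points (e.g. 1.35) sit.
* **Cut-point CIs**: stratified percentile bootstrap (B = 2000, seeded);
  the published tables print 95% CIs without stating a method, so the
  bootstrap is a package choice.
* **DeLong paired test**: placement-value covariance estimator, two-sided
  normal p; degenerate zero-variance comparisons (identical scores) return
  p = 1.
* **Binormal oracles**: closed-form AUC $\Phi(\Delta/\sqrt{\sigma_0^2 +
  \sigma_1^2})$ and density-crossing Youden cut are included for testing and
  power analysis.
* **Tau positivity**: strictly greater than the cut-point.

Cut-points are derived on AD vs amyloid-negative CU for the CU contrast
(the stated derivation rule), and on the contrast's own groups for AD vs
non-AD (`cutpoint_scope = "per_contrast"`, the default, which matches how
per-contrast cut-points are tabulated); `"ad_vs_abneg_cu"` reuses the
CU-derived cut-point everywhere, since published practice is ambiguous.

## Numerical and reporting choices

* Seeds: every stochastic step takes an explicit seed; the pipeline derives
  per-tracer/contrast/ROI sub-seeds from the master seed and records them.
* Determinism: identical configuration and seed give byte-identical cohorts
  and serialized reports.
* Rounding in human-readable output: AUC 3 decimals, cut-points 2 decimals,
  sensitivity/specificity 1 decimal.
* The cross-tracer "common cut-off" is the arithmetic mean of per-tracer
  cut-points, rounded to 2 decimals; applied to the published temporal
  meta-ROI AD-vs-non-AD cut-points (1.36, 1.34, 1.34) it gives 1.35 SUVR.
* Degenerate inputs (empty groups, single-class labels, zero-variance
  regions, zero total volume) raise errors naming the offending field; an
  empty contrast group in the pipeline is skipped with a warning.

## Problem sizes used in tests and scripts

The analysis scripts and the acceptance checks run the full pipeline on the
three preset cohorts at their published sizes (975/493/287) with B = 2000
bootstrap resamples, 500 trees and 10 folds. Unit tests use a reduced atlas
(18 labels) and smaller cohorts, trees and B so that the whole suite stays
fast; statistical acceptance checks use the replicate counts stated with
each test (e.g. 200 replicates for cut-point recovery, 1000 null simulations
for DeLong calibration, 11 replicates for the equal-variance cut-point
limit, whose single-draw estimator converges only at a cube-root rate).

## Known limitations

* Calibration matches first moments well and second moments approximately;
  simulated AUCs are therefore close to, but not guaranteed to reproduce,
  published AUC values.
* The RO948-like preset is the hardest case: its published pattern (CU
  matching non-AD in every temporal composite while sitting 0.15 SUVR above
  non-AD in the neocortex, with 43% amyloid-positive CU) cannot be matched
  exactly by a shared-onset single-latent model. The frozen preset keeps all
  group means within tolerance at the cost of inflated CU SDs and compressed
  AD SDs, so this preset's simulated Youden cut-points sit above the
  published ones and its AD-vs-CU AUC below; the flortaucipir- and
  MK6240-like presets do not share this distortion.
* The data-driven selection on synthetic cohorts concentrates on the
  strongest temporal-limbic regions; exact region lists from real cohorts
  are not reproducible by construction and are treated as documentation
  examples, not tests.
* Sensitivity/specificity CIs are bootstrap percentiles; exact binomial
  intervals are not implemented.
* The generator emits cross-sectional cohorts only; longitudinal accumulation
  is out of scope.
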