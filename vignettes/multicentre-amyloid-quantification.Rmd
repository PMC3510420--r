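---
title: "Multicentre amyloid-PET quantification on synthetic cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicentre amyloid-PET quantification on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amypet)
```

## The problem

Pooled multicentre [11C]PIB PET studies quantify fibrillar amyloid load as
a *retention ratio* (SUVR): regional tracer uptake in a late static window
divided by uptake in cerebellar grey matter, a region essentially devoid
of fibrillar amyloid. On top of that single number per region sit all the
clinically interesting questions — how cleanly the ratio separates
Alzheimer's disease (AD), mild cognitive impairment (MCI) and healthy
controls recruited at *different* centres with different scanners, doses
and reconstructions; where the normative positivity cutoff lies; and
whether a positive scan in MCI predicts conversion to AD.

No raw data from such studies are public. `amypet` therefore couples a
**synthetic-cohort generator** — digital phantoms rendered directly in a
common template space with centre-specific blur, noise, dose and axial
field of view — to a faithful re-implementation of the full
quantification and analysis chain, so that every step can be validated
against ground truth and against hand-computed oracles.

## The quantification chain

Per subject, in order:

1. **Frame integration.** Frames whose `[start, end)` interval lies
   entirely inside the 40–60 min window are summed (`integrate_frames()`).
   The containment rule is strict: a frame straddling the boundary is
   discarded. 40–60 min is the maximal window common to all centres.
2. **Grey-matter mask.** Ten template subjects' grey-matter probability
   maps are summed and thresholded at 50 % (`build_gm_mask()`; a voxel
   survives iff its mean probability is ≥ 0.5, inclusive at the boundary),
   then eroded by two voxels (`erode_mask()`). We read "two voxels in all
   dimensions" as two iterations of 6-connected (face-neighbour) erosion;
   a single-pass cubic-element alternative is exposed via
   `method = "box"` since the structuring element is a genuine free choice.
3. **ROI extraction.** The eroded mask is intersected with a 23-region
   grey-matter label atlas plus the cerebellar reference
   (`intersect_atlas()`). Empty regions are flagged, never silently
   dropped.
4. **Cerebellar scaling.** The reference value is the *median* voxel value
   under the cerebellar mask (`cerebellar_median()`) — the median, not the
   mean, because the lowermost PET slices can carry high voxel variance;
   the estimator must be insensitive to a minority of wild voxels (a
   property the tests assert directly: 49 % poisoned voxels move it not at
   all). The integral image divided by this scalar is the retention-ratio
   image (`ratio_image()`).
5. **Regional retention.** Cortical ROI values are arithmetic means of the
   ratio image (the median is motivated for the cerebellum specifically,
   so the cortex uses the mean); the primary readout is the *neocortical
   composite* — the unweighted mean of the frontal, parietal and
   lateral/basal temporal ROI means (`neocortical_composite()`).
6. **QC.** A subject is excluded when strictly more than 25 % of the
   cerebellar reference lies outside the axial field of view
   (`check_fov()`; exactly 25 % is retained — "more than" is read
   literally). Exclusions are tallied by reason in the pipeline manifest,
   which also carries slots for the two exclusion reasons the generator
   does not model (normalization failure, clinical re-diagnosis), so the
   accounting structure mirrors a real study's.

A sample-based template (`build_template()`) is the voxelwise mean of the
scaled images; spatial normalization itself is out of scope — phantoms are
born in template space.

## The normative cutoff

The positivity threshold is derived from the control distribution alone:

* `main_cluster()` — iterative upper trimming: compute mean + 2 SD, drop
  values strictly above, repeat to convergence. This isolates the majority
  subgroup of controls with normally distributed retention, treating
  high-retention controls as contaminants of the normative sample. A
  two-component Gaussian-mixture EM alternative is available behind
  `method = "mixture"` for sensitivity analysis.
* `normal_upper_limit()` — cutoff = cluster mean + 1.96 × SD, the upper
  bound of the central 95 % normal range. We deliberately do *not* read
  "upper 95 % confidence limit" as a confidence interval of the mean
  (which would be ≈ mean + 0.02, far below any plausible positivity
  threshold) nor as a one-sided 1.645 SD limit; the multiplier is a
  configurable argument. With the published cluster (1.26 ± 0.07) the rule
  gives 1.397, which prints as 1.40 at two decimals; the published 1.41 is
  consistent with the unrounded mean/SD of the real data.
* `classify_pib()` — positive iff strictly above the cutoff; ties are
  negative (negatives are defined by "ratio < cutoff", so the boundary
  value cannot be positive).

Two mathematical caveats worth knowing, both asserted in tests:

* The trimming rule is conservative at small n: a single extreme value
  among five (z = 1.79) is *not* trimmed, because one observation cannot
  exceed mean + 2 SD in so small a sample.
* The cutoff is **not** globally monotone in a single observation:
  d cutoff/d x_i = 1/n + 1.96 (x_i − mean)/((n−1) sd), which is negative
  for values far below the mean — raising them shrinks the SD faster than
  it lifts the mean. The tests assert the true directional properties
  (raising the top in-cluster value lifts the cutoff; raising an
  already-trimmed outlier changes nothing).

## The synthetic world

The generator's defaults *are* the published study conditions; they are
stated once and not tuned.

**Retention mixtures.** Each group's true neocortical composite is a
two-component (amyloid-negative/-positive) normal mixture:

| group | total mean ± SD | weight⁺ | negative component | positive component |
|---|---|---|---|---|
| controls | — | 5/51 | 1.26 ± 0.07 | 1.674 ± 0.108 (the five printed outlier values) |
| MCI | 1.64 ± 0.35 | 0.65 | 1.26 ± 0.07 | 1.845 ± 0.257 (moment-matched) |
| AD | 1.85 ± 0.32 | 0.90 | 1.30 ± 0.08 | 1.911 ± 0.275 (moment-matched) |

`moment_match_mixture()` solves the positive component from the law of
total variance so the mixture reproduces the published total mean and SD
*exactly*. A consequence the user should understand: because the
components overlap the 1.41 cutoff, the population exceedance fractions
are 87.8 % (AD) and 62.6 % (MCI), not the headline 90 %/65 % — the
published positivity rates and the published moments cannot be satisfied
simultaneously by overlapping normal components. The package prioritizes
the moments (they drive every downstream statistic) and reports the
closed-form exceedance via `mixture_positive_fraction()`; the acceptance
suite checks the rendered pipeline against both yardsticks and documents
which one it can meet.

**Regional truth.** All cortical and subcortical amyloid-coupled regions
carry the subject's composite value; the hippocampus is drawn from the
control-like low distribution in *every* group, implementing the null
hippocampal finding of PET-template-based analyses; cerebellum ≡ 1.0 by
construction; white matter is fixed at 1.8 as a nonspecific-binding
look-alike.

**Centres.** Five profiles (A–E) mirror the published acquisition
listing: centre A contributes six 5-min frames 40–70 min, the others
60–90 min dynamic series; dose scales are the published mean injected
doses relative to centre A. PSF FWHM (6–7.5 mm) and proportional noise
(5–8 %) are plausible per-scanner placeholders — the study reports no
per-centre reconstruction parameters, and the generator deliberately puts
*no* true centre effect on the ratios, so the diagnosis-vs-centre variance
partition has a known null to recover. Subjects are allocated to centres
with the published per-group counts.

**Cognition.** Scores are linear in the true composite with group-specific
intercepts fixed by the published group means. Delayed verbal recall uses
the published group slopes (−0.5/−2.34/−0.82 Z per ratio unit); its
residual SD (1.134) and the common MMSE slope (−1.335) are solved in
closed form (`calibrate_cognition()`) so the *pooled* correlations match
r = −0.60 and −0.45 — pooled over the tested subset (n = 38/64/90 per
group for delayed recall, the printed n = 192), which matters: weighting
by full group sizes instead biases the pooled r by ≈ 0.015. Scores are
missing at random at the published per-test availability; MMSE is rounded
and clipped to 0–30, which truncates the control mean by ≈ 0.1 point.

**ApoE.** Carrier frequencies are the published per-group fractions
(10/31, 34/59, 48/85); genotyping is absent at centre C. MCI carriers
receive positive-component weight 0.80, with the non-carrier weight solved
so the marginal stays 0.65.

**Follow-up and conversion.** 64/72 MCI are followed for
Normal(28, 15) months clipped to 6–60. PIB-positive MCI convert with a
latent exponential of monthly hazard 0.0445 (chosen so the crude converted
fraction at that censoring is ≈ 0.674); negatives have hazard 0, making
the 100 % negative predictive value a structural property. Note the
published crude fraction (67.4 %) and KM median (24 months) are not
jointly attainable under one exponential hazard with this censoring — the
generator prioritizes the crude fraction, and the KM-median acceptance
study instead uses the stated rate-ln(2)/24 design, which is about the
estimator, not the cohort.

## Phantom rendering and its limits

`render_phantom()` produces, per frame, dose × (label image of true
ratios) convolved with the centre's isotropic Gaussian PSF, plus Gaussian
noise with SD proportional to the local blurred signal, with out-of-FOV
slices masked. Because the phantom is piecewise-constant, convolution is
implemented as a cached matrix product over blurred label indicators —
mathematically identical to blurring the rendered image (linearity), and
fast enough to render ~43 000 subjects in the Monte-Carlo acceptance
studies. Frames are statistically independent renderings of one static
map: there are **no tracer kinetics**, no motion, no registration error,
no attenuation/scatter artefacts, and noise is Gaussian rather than
Poisson-like. A green end-to-end test therefore establishes that the
*quantification chain* is unbiased and correctly seeded under the stated
imaging physics — not that it would survive real-world normalization
failures, which enter the pipeline only as bookkeeping slots.

Erosion is what makes the chain essentially unbiased here: after two
erosion iterations the surviving ROI voxels sit ≥ 2 voxels from any
tissue boundary, and with σ ≈ 2.5–3.2 mm the point-spread kernel's mass
beyond that distance is negligible. The tests exercise the converse too:
on an *uneroded* mask the frontal ROI inflates monotonically with FWHM
(its shell borders hotter white matter), reproducing the partial-volume
effect the erosion exists to suppress.

## Numerical choices and degenerate inputs

* 50 % threshold inclusive, with a 1e−9 tolerance so an exact 0.5 mean
  survives floating-point accumulation.
* Median with even counts = mean of the two central order statistics
  (`stats::median`).
* Kaplan-Meier via the survival package: Greenwood SEs; median = first
  time S(t) ≤ 0.5; mean reported as the restricted mean to the largest
  observed time; at tied times events precede censorings. The log-rank
  test is Mantel-Cox, validated against an explicit risk-table oracle.
* Annual conversion rate = 100 × (1 − S_KM(12 mo)); a person-years
  estimate is reported alongside because a single published "annual rate"
  rarely states its derivation.
* Two-way variance partition uses Type II sums of squares (each main
  effect adjusted for the other) with η² relative to the total SS — the
  design is unbalanced with empty diagnosis × centre cells, which Type II
  tolerates; it reduces exactly to the one-way ANOVA when the second
  factor is constant.
* Zero-variance inputs: ANOVA flags an infinite F; the cutoff falls back
  to the cluster mean with a warning; correlation and regression refuse
  zero-variance variables.
* Reduced-resolution Monte-Carlo rendering uses a 40 × 40 × 30 grid at
  4.8 mm (same 192 × 192 × 144 mm field as the 64 × 64 × 48 × 3 mm
  default); at that resolution some small subcortical nuclei do not
  survive two-voxel erosion and are flagged empty — the composite regions
  all survive, which is what the studies measure.
* All randomness flows through explicit seeds; a master seed fans out to
  per-stage child seeds (`seed × 48271 + stage × 7919 mod 2³¹−1`) so
  stages can be re-run in isolation and the whole pipeline is
  byte-reproducible.

## Known limitations

* The atlas is a drawn ellipsoidal parcellation, not an anatomical atlas;
  region adjacencies (hence partial-volume mixing patterns) are only
  qualitatively brain-like.
* Centre PSF/noise values are placeholders; conclusions about *specific*
  between-centre differences are outside what the generator can support.
* The positivity-rate vs mixture-moment tension described above is
  irreducible within two-component normal mixtures.
* Spatial normalization, MRI segmentation of real images, tracer
  kinetics and radiochemistry are all out of scope by design.

## A worked micro-example

```{r example, eval = FALSE}
library(amypet)
res <- run_pipeline(generator_config(), seed = 11)
res$threshold          # trimmed-control cutoff, e.g. 1.375
res$stats$positivity_pct
res$survival$conversion$npv_pct   # 100 whenever negatives have hazard 0
```

The numbered scripts under `analysis/` run exactly this workflow stage by
stage and write their tables under `results/`; `scripts/acceptance.R`
re-runs the three Monte-Carlo validation studies from scratch.
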