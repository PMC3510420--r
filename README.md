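# amypet

Multicentre amyloid-PET ([11C]PIB) retention-ratio quantification,
normative-cutoff derivation and MCI-conversion survival analysis, built as
a fully synthetic, fully testable pipeline.

Pooled multicentre amyloid PET studies rest on one number per region: the
**retention ratio** (SUVR),

    SUVR_region = mean 40-60 min uptake in region / median 40-60 min uptake in cerebellar grey matter,

with the primary readout being the **neocortical composite** — the
unweighted mean over frontal, parietal and lateral/basal temporal regions
— and a **normative positivity cutoff** derived from the control
distribution as

    cutoff = mean + 1.96 x SD   of the trimmed ("main cluster") control composites.

Subjects above the cutoff are PIB-positive; in MCI, positivity is the
predictor in a Kaplan-Meier dementia-free survival analysis (log-rank
Mantel-Cox, negative predictive value, annual conversion rate).

Because no raw data from such studies are public, `amypet` pairs the
quantification chain with a calibrated synthetic world: a ground-truth
cohort generator (two-component retention mixtures per diagnostic group,
ApoE coupling, retention-coupled cognition, exponential conversion times)
and a phantom renderer (template-space label atlas, per-centre Gaussian
PSF, proportional noise, dose scaling, frame schedules, axial
field-of-view truncation). Every stage is validated against ground truth,
hand-computed oracles, and Monte-Carlo recovery studies. Who it is for:
anyone who wants a transparent, reproducible desk-scale model of the
multicentre SUVR workflow — to test analysis choices (erosion depth,
reference statistic, cutoff multiplier) against a known truth.

## A worked run

The numbered scripts under `analysis/` execute the workflow stage by
stage, writing tables to `results/`:

```sh
Rscript analysis/01_simulate.R     # ground-truth cohort (220 subjects, centres A-E)
Rscript analysis/02_mask.R         # GM mask: threshold 50 %, erode 2 voxels, 23 ROIs
Rscript analysis/03_quantify.R     # render phantoms, integrate 40-60 min, SUVR
Rscript analysis/04_classify.R     # trimmed-control cutoff, classification
Rscript analysis/05_group_stats.R  # ANOVA, variance partition, cognition relations
Rscript analysis/06_survival.R     # conversion, NPV, Kaplan-Meier, log-rank
```

Output of one complete run (seed 11), lightly abridged:

```
simulated 220 subjects                      # 51 controls / 72 MCI / 97 AD
grey-matter mask: 40816 voxels; 22358 after erosion
composite recovery: bias +0.0019, RMS error 0.0038
threshold_model: cutoff 1.3753 = 1.2499 + 1.96 x 0.0640 (n = 49, 2 excluded)
PIB-positive fractions (%):  AD 88.7   control 3.9   MCI 69.4
diagnosis ANOVA: F(2,217) = 66.0, p = 4e-23
variance partition: eta2 diagnosis/centre = 45.7
r(composite, delayed recall) = -0.61 (n = 191)
delayed-recall slope: MCI -3.03 (SE 0.45), AD -0.77 (SE 0.30)
MCI with follow-up: 66 (44 positive, 22 negative)
crude conversion among positives: 65.9 %
NPV of a negative scan: 100.0 %
log-rank positive vs negative: chi2 = 22.7, p = 1.8e-06
log-rank high vs low positive: chi2 = 0.03, p = 0.85
```

Reading it: phantom rendering + masking + cerebellar-median scaling
recover each subject's true composite to ~0.004; the trimmed-control rule
puts the cutoff near 1.38 (the population value of the rule is
1.26 + 1.96 x 0.07 = 1.397); the three diagnostic groups separate strongly
while the centre effect is an order of magnitude weaker; retention couples
to delayed recall pooled across groups but not within the positive
stratum; and no PIB-negative MCI subject converts, so a negative scan has
100 % negative predictive value in this world by construction.

The same pipeline is available as one call:

```r
library(amypet)
res <- run_pipeline(generator_config(), seed = 11)
```

## Acceptance studies

`scripts/acceptance.R` recomputes the calibration-recovery quantities from
scratch against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It runs three Monte-Carlo studies — (1) the normative cutoff over 1000
simulated control arms (46 normative controls plus the five published
outlier values, trimming then mean + 1.96 SD); (2) end-to-end group-mean
and positivity recovery through phantom rendering and quantification at
reduced image size over 200 seeded replicates of the control/MCI/AD arms;
(3) the Kaplan-Meier median for an exponential with a 24-month median
under the study's censoring over 500 replicates — and writes one JSON
object with the resulting values. Expect roughly 10 minutes on one CPU;
everything is driven by `--seed`.

## Layout

- `R/` — the package: generator (`sample_cohort`, `render_phantom`),
  masking (`build_gm_mask`, `erode_mask`, `intersect_atlas`),
  quantification (`integrate_frames`, `cerebellar_median`, `ratio_image`,
  `regional_means`, `neocortical_composite`), cutoff (`main_cluster`,
  `normal_upper_limit`, `classify_pib`), statistics (`anova_oneway`,
  `variance_partition`, `pearson_r`, `ols_slope`,
  `chi_squared_proportions`), survival (`km_estimate`, `logrank`,
  `conversion_summary`), orchestration (`run_pipeline`) and the
  Monte-Carlo studies (`mc_*_study`).
- `analysis/` — the numbered workflow drivers shown above.
- `vignettes/multicentre-amyloid-quantification.Rmd` — models,
  assumptions, calibration derivations, numerical choices, limitations.
- `tests/testthat/` — unit, property and acceptance suites.
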