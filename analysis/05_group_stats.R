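#!/usr/bin/env Rscript
# Stage 5: group-level statistics on measured retention - diagnosis ANOVA,
# diagnosis-vs-centre variance partition, retention-cognition relations,
# ApoE contingency.
suppressPackageStartupMessages(library(amypet))

d <- read.csv("results/cohort_classified.csv")
d <- d[!d$qc_excluded, ]
d$diagnosis <- factor(d$diagnosis, levels = c("control", "MCI", "AD"))

stats <- list(
  anova_composite = anova_oneway(d$composite, d$diagnosis),
  variance_partition = variance_partition(d$composite, d$diagnosis, d$centre),
  r_verbal_delayed = pearson_r(d$composite, d$verbal_del_z),
  r_mmse = pearson_r(d$composite, d$mmse),
  slope_MCI = with(d[d$diagnosis == "MCI", ], ols_slope(composite, verbal_del_z)),
  slope_AD = with(d[d$diagnosis == "AD", ], ols_slope(composite, verbal_del_z)),
  apoe = chi_squared_proportions(table(d$apoe_e4[!is.na(d$apoe_e4)],
                                       d$diagnosis[!is.na(d$apoe_e4)]))
)
jsonlite::write_json(stats, "results/group_stats.json",
                     auto_unbox = TRUE, digits = NA, force = TRUE)

with(stats, {
  cat(sprintf("diagnosis ANOVA: F(%d,%d) = %.1f, p = %.2g\n",
              anova_composite$df_between, anova_composite$df_within,
              anova_composite$F, anova_composite$p))
  cat(sprintf("variance partition: eta2 diagnosis/centre = %.1f\n",
              variance_partition$eta_ratio))
  cat(sprintf("r(composite, delayed recall) = %.2f (n = %d)\n",
              r_verbal_delayed$r, r_verbal_delayed$n))
  cat(sprintf("r(composite, MMSE) = %.2f\n", r_mmse$r))
  cat(sprintf("delayed-recall slope: MCI %.2f (SE %.2f), AD %.2f (SE %.2f)\n",
              slope_MCI$slope, slope_MCI$se, slope_AD$slope, slope_AD$se))
  cat(sprintf("ApoE x diagnosis: chi2 = %.1f, p = %.3g\n", apoe$chi_sq, apoe$p))
})
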