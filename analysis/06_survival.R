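#!/usr/bin/env Rscript
# Stage 6: MCI follow-up - crude conversion, NPV, annual rate, Kaplan-Meier
# curves and log-rank contrasts (positive vs negative; high vs low positive).
suppressPackageStartupMessages(library(amypet))

d <- read.csv("results/cohort_classified.csv")
d <- d[!d$qc_excluded, ]
conv <- conversion_summary(d)

mci <- d[d$diagnosis == "MCI" & !is.na(d$followup_months), ]
tt <- ifelse(mci$converted, mci$conversion_month, mci$followup_months)
pos <- mci$classification == "positive"
lr <- logrank(tt[pos], mci$converted[pos], tt[!pos], mci$converted[!pos])

sp <- split_high_low(mci$composite[pos])
tp <- tt[pos]; cp <- mci$converted[pos]
lr_hl <- logrank(tp[sp$high], cp[sp$high], tp[sp$low], cp[sp$low])

out <- list(conversion = conv, logrank_pos_vs_neg = lr,
            logrank_high_vs_low = lr_hl)
jsonlite::write_json(out, "results/survival.json",
                     auto_unbox = TRUE, digits = NA, force = TRUE)

cat(sprintf("MCI with follow-up: %d (%d positive, %d negative)\n",
            nrow(mci), conv$n_positive, conv$n_negative))
cat(sprintf("crude conversion among positives: %.1f %%\n",
            conv$crude_pct_positive_converted))
cat(sprintf("NPV of a negative scan: %.1f %%\n", conv$npv_pct))
cat(sprintf("annual conversion rate (1 - S(12)): %.1f %% (person-years %.1f %%)\n",
            conv$annual_rate_pct, conv$person_years_rate_pct))
cat(sprintf("KM median %.0f months, restricted mean %.0f +/- %.0f\n",
            conv$km_median, conv$km_restricted_mean, conv$km_restricted_mean_se))
cat(sprintf("log-rank positive vs negative: chi2 = %.1f, p = %.2g\n",
            lr$chi_sq, lr$p))
cat(sprintf("log-rank high vs low positive: chi2 = %.2f, p = %.2f\n",
            lr_hl$chi_sq, lr_hl$p))
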