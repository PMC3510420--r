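#!/usr/bin/env Rscript
# Stage 4: derive the normative cutoff from the included controls
# (iterative trimming, then mean + 1.96 SD) and classify everyone.
suppressPackageStartupMessages(library(amypet))

cohort <- read.csv("results/cohort_truth.csv")
retention <- read.csv("results/retention.csv")
merged <- cbind(cohort, retention[setdiff(names(retention),
                                          c("subject_id", "centre"))])
included <- merged[!merged$qc_excluded, ]

thr <- derive_threshold(included$composite[included$diagnosis == "control"])
print(thr)
merged$classification <- classify_pib(merged$composite, thr$cutoff)
write.csv(merged, "results/cohort_classified.csv", row.names = FALSE)
jsonlite::write_json(thr[c("cluster_mean", "cluster_sd", "cluster_n",
                           "multiplier", "cutoff", "excluded_controls")],
                     "results/threshold.json", auto_unbox = TRUE, digits = NA)

pos <- with(merged[!merged$qc_excluded, ],
            tapply(classification == "positive", diagnosis, mean))
cat("PIB-positive fractions (%):\n")
print(round(100 * pos, 1))
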