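#!/usr/bin/env Rscript
# Derives the cognition-coupling constants (delayed-recall residual SD and
# the common MMSE slope) by closed-form pooled-moment matching, and checks
# them against the values frozen in default_cognition_model().
suppressPackageStartupMessages(library(amypet))

cal <- calibrate_cognition()
frozen <- default_cognition_model()

cat(sprintf("delayed-recall residual SD : solved %.4f, frozen %.4f\n",
            cal$sigma_verbal_del, frozen$verbal_del$resid_sd[["MCI"]]))
cat(sprintf("MMSE slope                 : solved %.4f, frozen %.4f\n",
            cal$mmse_slope, frozen$mmse$slopes[["MCI"]]))
cat(sprintf("MMSE residual SDs          : solved %s, frozen %s\n",
            paste(sprintf("%.4f", cal$mmse_resid_sd), collapse = "/"),
            paste(sprintf("%.4f", frozen$mmse$resid_sd), collapse = "/")))

stopifnot(abs(cal$sigma_verbal_del - frozen$verbal_del$resid_sd[["MCI"]]) < 5e-4,
          abs(cal$mmse_slope - frozen$mmse$slopes[["MCI"]]) < 5e-4)
cat("frozen constants reproduce the closed-form calibration\n")
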