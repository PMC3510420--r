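# cohort generator: mixtures, determinism, calibration recovery

test_that("moment matching reproduces the requested total moments", {
  # trivial single component
  m1 <- moment_match_mixture(1.5, 0.2, weight_pos = 1, neg_mean = 9, neg_sd = 9)
  expect_equal(c(m1$pos_mean, m1$pos_sd), c(1.5, 0.2))

  # the two calibrated group mixtures, checked against a large Monte-Carlo
  # draw (10^6): sample moments must recover the configured totals
  cases <- list(list(1.85, 0.32, 0.90, 1.30, 0.08),
                list(1.64, 0.35, 0.65, 1.26, 0.07))
  for (cs in cases) {
    mix <- moment_match_mixture(cs[[1]], cs[[2]], cs[[3]], cs[[4]], cs[[5]])
    # closed-form law-of-total-variance identity holds exactly
    w <- cs[[3]]
    m_tot <- w * mix$pos_mean + (1 - w) * cs[[4]]
    v_tot <- w * mix$pos_sd^2 + (1 - w) * cs[[5]]^2 +
      w * (mix$pos_mean - m_tot)^2 + (1 - w) * (cs[[4]] - m_tot)^2
    expect_equal(m_tot, cs[[1]], tolerance = 1e-12)
    expect_equal(sqrt(v_tot), cs[[2]], tolerance = 1e-12)
    draws <- amypet:::with_seed(42, amypet:::draw_mixture(1e6, mix)$value)
    expect_equal(mean(draws), cs[[1]], tolerance = 3 * cs[[2]] / sqrt(1e6) / cs[[1]])
    expect_equal(sd(draws), cs[[2]], tolerance = 0.003)
  }
  # frozen solved values for the AD calibration (verified above by MC)
  mAD <- moment_match_mixture(1.85, 0.32, 0.90, 1.30, 0.08)
  expect_equal(mAD$pos_mean, 1.911111, tolerance = 1e-6)
  expect_equal(mAD$pos_sd, 0.275174, tolerance = 1e-5)

  expect_error(moment_match_mixture(1.30, 0.05, 0.5, 1.30, 0.30),
               "infeasible")
})

test_that("cohort sampling is deterministic and reproducible", {
  cfg <- small_config()
  a <- sample_cohort(cfg, seed = 11)
  b <- sample_cohort(cfg, seed = 11)
  expect_identical(a, b)
  # byte-identical CSV
  f1 <- tempfile(); f2 <- tempfile()
  write.csv(a, f1, row.names = FALSE); write.csv(b, f2, row.names = FALSE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  c2 <- sample_cohort(cfg, seed = 12)
  expect_false(identical(a$true_composite, c2$true_composite))
})

test_that("degenerate mixture collapses every control to the negative mean", {
  mixes <- default_mixtures()
  mixes$control$weight_pos <- 0
  mixes$control$neg_sd <- 0
  cfg <- generator_config(group_sizes = c(control = 20, MCI = 5, AD = 5),
                          mixtures = mixes)
  co <- sample_cohort(cfg, seed = 4)
  expect_true(all(co$true_composite[co$diagnosis == "control"] == 1.26))
})

test_that("large-sample MCI positivity matches the configured mixture", {
  cfg <- generator_config(group_sizes = c(control = 5, MCI = 10000, AD = 5))
  co <- sample_cohort(cfg, seed = 9)
  mci <- co[co$diagnosis == "MCI", ]
  # the configured component weight governs component membership ...
  expect_equal(mean(mci$component == "pos"), 0.65, tolerance = 0.01)
  # ... while the fraction above the 1.41 cutoff converges to the
  # closed-form mixture tail (components overlap the cutoff slightly)
  p_tail <- mixture_positive_fraction(default_mixtures()$MCI, 1.41)
  expect_equal(mean(mci$true_composite > 1.41), p_tail, tolerance = 0.015)
})

test_that("group mixture moments are recovered at n = 1e5", {
  cfg <- generator_config(group_sizes = c(control = 1e5, MCI = 1e5, AD = 1e5))
  co <- sample_cohort(cfg, seed = 21)
  for (g in c("control", "MCI", "AD")) {
    mom <- amypet:::mixture_moments(cfg$mixtures[[g]])
    x <- co$true_composite[co$diagnosis == g]
    se_mean <- sqrt(mom["var"] / length(x))
    expect_lt(abs(mean(x) - mom["mean"]), 3 * se_mean)
    expect_equal(sd(x), sqrt(unname(mom["var"])), tolerance = 0.02)
  }
})

test_that("ground-truth invariants hold across seeds", {
  cfg <- generator_config(group_sizes = c(control = 30, MCI = 60, AD = 40))
  for (seed in 1:5) {
    co <- sample_cohort(cfg, seed = seed)
    expect_true(all(co$ratio_cerebellum == 1))
    expect_true(all(co$ratio_white_matter == 1.8))
    # hippocampal truth stays control-like (low) in every diagnostic group
    expect_true(all(co$ratio_hippocampus_L < 1.26 + 5 * 0.07))
    expect_gt(0.05, abs(mean(c(co$ratio_hippocampus_L, co$ratio_hippocampus_R)) - 1.26))
    # conversion confined to PIB-positive MCI, inside follow-up
    conv <- co[!is.na(co$converted) & co$converted, ]
    expect_true(all(conv$true_composite > cfg$cutoff))
    expect_true(all(conv$conversion_month <= conv$followup_months))
    expect_true(all(is.na(co$converted[co$diagnosis != "MCI"])))
  }
})

test_that("ApoE e4 carriers in MCI are enriched for amyloid positivity", {
  cfg <- generator_config(group_sizes = c(control = 5, MCI = 20000, AD = 5))
  co <- sample_cohort(cfg, seed = 31)
  mci <- co[co$diagnosis == "MCI" & !is.na(co$apoe_e4), ]
  p_car <- mean(mci$component[mci$apoe_e4] == "pos")
  p_non <- mean(mci$component[!mci$apoe_e4] == "pos")
  expect_equal(p_car, 0.80, tolerance = 0.02)
  expect_gt(p_car, p_non + 0.2)
  # marginal positivity preserved
  all_mci <- co[co$diagnosis == "MCI", ]
  expect_equal(mean(all_mci$component == "pos"), 0.65, tolerance = 0.015)
})

test_that("cognition coupling recovers the calibrated pooled correlations", {
  cfg <- generator_config(group_sizes = c(control = 5100, MCI = 7200, AD = 9700))
  co <- sample_cohort(cfg, seed = 17)
  r_del <- pearson_r(co$true_composite, co$verbal_del_z)
  expect_equal(r_del$r, -0.60, tolerance = 0.03)
  r_mmse <- pearson_r(co$true_composite, co$mmse)
  expect_equal(r_mmse$r, -0.45, tolerance = 0.04)
  # group means of delayed recall match the published table
  gm <- tapply(co$verbal_del_z, co$diagnosis, mean, na.rm = TRUE)
  expect_equal(as.numeric(gm), c(0.9, -1.2, -2.2), tolerance = 0.08)
  mm <- tapply(co$mmse, co$diagnosis, mean, na.rm = TRUE)
  expect_equal(as.numeric(mm), c(29.2, 27.1, 24.0), tolerance = 0.25)
})
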