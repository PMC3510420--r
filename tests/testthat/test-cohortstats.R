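# group statistics: ANOVA, variance partition, correlation, chi-squared

test_that("one-way ANOVA matches the hand-computed F", {
  # groups {0,1} and {2,3}: SSB = 4, SSW = 1, F = (4/1)/(1/2) = 8
  a <- anova_oneway(c(0, 1, 2, 3), c("g1", "g1", "g2", "g2"))
  expect_equal(a$F, 8, tolerance = 1e-12)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 2)
  expect_equal(a$p, pf(8, 1, 2, lower.tail = FALSE), tolerance = 1e-12)

  # identical groups: F = 0, p = 1
  b <- anova_oneway(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(b$F, 0, tolerance = 1e-12)
  expect_equal(b$p, 1, tolerance = 1e-12)

  # SS decomposition invariant
  set.seed(3)
  y <- rnorm(60); g <- sample(letters[1:3], 60, TRUE)
  fit <- anova_oneway(y, g)
  sst <- sum((y - mean(y))^2)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2))
  ssw <- sst - ssb
  expect_equal(fit$F, (ssb / fit$df_between) / (ssw / fit$df_within),
               tolerance = 1e-8)
})

test_that("diagnostic-group separation is reliably detected in the cohort", {
  cfg <- generator_config()
  hits <- 0L
  for (seed in 1:200) {
    co <- sample_cohort(cfg, seed = seed)
    a <- anova_oneway(co$true_composite, co$diagnosis)
    ordered <- a$group_means[["AD"]] > a$group_means[["MCI"]] &&
      a$group_means[["MCI"]] > a$group_means[["control"]]
    if (a$p < 0.001 && ordered) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("two-way variance partition matches hand arithmetic on a 2x2 table", {
  # balanced table: SS_A = 32, SS_B = 8, SS_int = 0, SS_resid = 2
  y <- c(1, 2, 3, 4, 5, 6, 7, 8)
  a <- rep(c("a1", "a2"), each = 4)
  b <- rep(c("b1", "b1", "b2", "b2"), 2)
  vp <- variance_partition(y, a, b)
  expect_equal(vp$a$ss, 32, tolerance = 1e-10)
  expect_equal(vp$b$ss, 8, tolerance = 1e-10)
  expect_equal(vp$interaction$ss, 0, tolerance = 1e-10)
  expect_equal(vp$residual$ss, 2, tolerance = 1e-10)
  expect_equal(vp$a$eta_sq, 32 / 42, tolerance = 1e-10)
  expect_equal(vp$b$eta_sq, 8 / 42, tolerance = 1e-10)

  # response depending only on factor a: eta_b = 0
  y2 <- ifelse(a == "a1", 1, 5) + c(0.1, -0.1, 0.1, -0.1, 0.1, -0.1, 0.1, -0.1)
  vp2 <- variance_partition(y2, a, b)
  expect_equal(vp2$b$eta_sq, 0, tolerance = 1e-10)

  # single-level factor_b reduces to the one-way ANOVA
  ow <- anova_oneway(y, a)
  vp3 <- variance_partition(y, a, rep("only", 8))
  expect_equal(vp3$a$F, ow$F, tolerance = 1e-10)
  expect_equal(vp3$a$p, ow$p, tolerance = 1e-10)
})

test_that("diagnosis dominates centre in the variance partition", {
  # the generator puts no true centre effect on retention ratios
  cfg <- generator_config()
  hits <- 0L
  for (seed in 1:200) {
    co <- sample_cohort(cfg, seed = 1000 + seed)
    vp <- variance_partition(co$true_composite, co$diagnosis, co$centre)
    if (vp$eta_ratio >= 4) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.90)
})

test_that("Pearson correlation and its edge cases", {
  expect_equal(pearson_r(c(0, 1, 2), c(0, 2, 1))$r, 0.5, tolerance = 1e-12)
  r1 <- pearson_r(1:10, 1:10)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  set.seed(4)
  x <- rnorm(20)
  expect_equal(pearson_r(x, -3 * x + 2)$r, -1, tolerance = 1e-12)
  expect_equal(pearson_r(x, 0.5 * x + 1)$r, 1, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 20)), "zero variance")
  # pairwise-complete n bookkeeping
  y <- rnorm(20); y[1:5] <- NA
  expect_equal(pearson_r(x, y)$n, 15)
})

test_that("pooled retention-memory correlation is recovered across seeds", {
  cfg <- generator_config()
  rs <- vapply(1:200, function(seed) {
    co <- sample_cohort(cfg, seed = 2000 + seed)
    pearson_r(co$true_composite, co$verbal_del_z)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - (-0.60)), 0.08)
})

test_that("least-squares slope matches the normal-equation solution", {
  f <- suppressWarnings(ols_slope(c(0, 1, 2), c(1, 3, 5))) # exact fit
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$se, 0, tolerance = 1e-12)
  expect_equal(ols_slope(c(0, 1, 2), c(0, 1, 3))$slope, 1.5, tolerance = 1e-12)
  expect_error(ols_slope(rep(2, 5), rnorm(5)), "zero variance")
})

test_that("restricting to positives attenuates the retention-memory link", {
  # within the positive MCI subgroup the composite spans a narrower range,
  # so the significance of the slope should collapse much more often
  cfg <- generator_config()
  sig_all <- sig_pos <- 0L
  for (seed in 1:100) {
    co <- sample_cohort(cfg, seed = 3000 + seed)
    mci <- co[co$diagnosis == "MCI" & !is.na(co$verbal_del_z), ]
    s_all <- ols_slope(mci$true_composite, mci$verbal_del_z)
    pos <- mci[mci$true_composite > 1.41, ]
    s_pos <- ols_slope(pos$true_composite, pos$verbal_del_z)
    sig_all <- sig_all + (s_all$p < 0.001)
    sig_pos <- sig_pos + (s_pos$p < 0.001)
  }
  expect_gte(sig_all / 100, 0.9)
  expect_lt(sig_pos, sig_all / 2)
})

test_that("Pearson chi-squared matches hand arithmetic", {
  # [[10,20],[20,10]]: all expected 15, chi2 = 4 * 25/15 = 6.667
  x <- chi_squared_proportions(rbind(c(10, 20), c(20, 10)))
  expect_equal(x$chi_sq, 20 / 3, tolerance = 1e-10)
  expect_equal(x$df, 1)

  # identical columns
  x2 <- chi_squared_proportions(rbind(c(10, 10), c(20, 20)))
  expect_equal(x2$chi_sq, 0, tolerance = 1e-12)
  expect_equal(x2$p, 1, tolerance = 1e-12)

  # published carrier counts, controls (10/31) vs AD (48/85): the oracle is
  # the explicit expected-count formula
  tab <- rbind(controls = c(carrier = 10, non = 21),
               AD = c(carrier = 48, non = 37))
  x3 <- chi_squared_proportions(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(x3$chi_sq, sum((tab - expected)^2 / expected), tolerance = 1e-10)
  expect_gt(48 / 85, 10 / 31)  # direction: carriers more frequent in AD
  expect_lt(x3$p, 0.05)

  expect_error(chi_squared_proportions(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("statistics are invariant to record order", {
  set.seed(9)
  y <- rnorm(40); g <- sample(c("a", "b", "c"), 40, TRUE)
  h <- sample(c("u", "v"), 40, TRUE)
  p <- sample(40)
  expect_equal(anova_oneway(y, g)$F, anova_oneway(y[p], g[p])$F, tolerance = 1e-10)
  expect_equal(variance_partition(y, g, h)$a$ss,
               variance_partition(y[p], g[p], h[p])$a$ss, tolerance = 1e-10)
  expect_equal(pearson_r(y, seq_along(y) * 0.1 + y)$r,
               pearson_r(y[p], (seq_along(y) * 0.1 + y)[p])$r, tolerance = 1e-10)
})
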