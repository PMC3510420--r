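# normative cutoff: trimming, upper limit, classification

test_that("iterative trimming isolates the main cluster", {
  # hand-run on {1 x 9, 10}: mean 1.9, sd 2.846, limit 7.59 -> 10 trimmed;
  # second pass on the constant rest removes nothing
  mc <- main_cluster(c(rep(1, 9), 10))
  expect_equal(sort(mc$cluster), rep(1, 9))
  expect_equal(mc$outliers, 10)
  expect_equal(mc$iterations, 1L)

  # a single extreme value in n = 5 stays below mean + 2 SD and is kept
  # (its z-score is 0.8/0.447 = 1.79): the rule is deliberately conservative
  mc5 <- main_cluster(c(1, 1, 1, 1, 10))
  expect_length(mc5$outliers, 0)

  # degenerate constant input returns everything
  mc2 <- main_cluster(rep(1.2, 5))
  expect_equal(mc2$cluster, rep(1.2, 5))
  expect_length(mc2$outliers, 0)

  # the cluster is always an order-statistic prefix of the sorted input
  set.seed(13)
  for (rep in 1:20) {
    x <- c(rnorm(40, 1.26, 0.07), runif(5, 1.5, 2.0))
    mc3 <- main_cluster(x)
    sx <- sort(x)
    expect_identical(sort(mc3$cluster), sx[seq_along(mc3$cluster)])
    expect_lte(mc3$iterations, length(x))
  }
})

test_that("published-style contaminants are trimmed in almost all arms", {
  st <- mc_cutoff_study(n_seeds = 200, seed = 77)
  expect_gte(st$outlier_detection_rate, 0.95)
})

test_that("the upper normal limit is mean + 1.96 SD of the cluster", {
  # two points engineered to mean 1.26, sd 0.07
  x <- c(1.26 - 0.07 / sqrt(2), 1.26 + 0.07 / sqrt(2))
  tm <- normal_upper_limit(x)
  expect_equal(tm$cluster_mean, 1.26, tolerance = 1e-12)
  expect_equal(tm$cluster_sd, 0.07, tolerance = 1e-12)
  expect_equal(tm$cutoff, 1.26 + 1.96 * 0.07, tolerance = 1e-12) # = 1.3972

  tm2 <- normal_upper_limit(c(0, 2))
  expect_equal(tm2$cutoff, 1 + 1.96 * sqrt(2), tolerance = 1e-12)

  expect_warning(tm3 <- normal_upper_limit(rep(1.3, 4)), "zero variance")
  expect_equal(tm3$cutoff, 1.3)

  # configurable multiplier
  tm4 <- normal_upper_limit(c(0, 2), multiplier = 1.645)
  expect_equal(tm4$cutoff, 1 + 1.645 * sqrt(2), tolerance = 1e-12)
})

test_that("cutoff responds to perturbations as the formula dictates", {
  # note: the cutoff is NOT globally monotone in a single observation -
  # raising a far-below-mean value shrinks the cluster SD faster than it
  # lifts the mean (d cutoff / d x_i = 1/n + 1.96 (x_i - mean)/((n-1) sd)),
  # and a raise can also move the value across the trim limit. True
  # directional properties:
  set.seed(29)
  for (rep in 1:30) {
    x <- c(rnorm(46, 1.26, 0.07), runif(3, 1.5, 1.9))
    t0 <- derive_threshold(x)

    # internal consistency: cutoff reproduces mean + 1.96 sd of the cluster
    expect_equal(t0$cutoff, t0$cluster_mean + 1.96 * t0$cluster_sd,
                 tolerance = 1e-12)
    # bookkeeping: cluster + excluded = input
    expect_equal(t0$cluster_n + length(t0$excluded_controls), length(x))
    expect_true(all(t0$excluded_controls > t0$cutoff))

    # raising the top in-cluster value (while it stays in-cluster) lifts
    # the cutoff: both mean and SD increase
    cl <- sort(setdiff_vals(x, t0$excluded_controls))
    top <- max(cl)
    i <- which(x == top)[1]
    x2 <- x
    x2[i] <- x2[i] + 0.005
    t1 <- derive_threshold(x2)
    if (t1$cluster_n == t0$cluster_n) expect_gte(t1$cutoff, t0$cutoff - 1e-12)

    # raising an already-trimmed outlier leaves the cutoff unchanged
    if (length(t0$excluded_controls) > 0) {
      j <- which(x == max(t0$excluded_controls))[1]
      x3 <- x
      x3[j] <- x3[j] + 1
      expect_equal(derive_threshold(x3)$cutoff, t0$cutoff, tolerance = 1e-12)
    }
  }
})

test_that("classification is strictly-greater with negative ties", {
  expect_equal(classify_pib(1.40, 1.41), "negative")
  expect_equal(classify_pib(1.85, 1.41), "positive")
  expect_equal(classify_pib(1.41, 1.41), "negative")
  expect_equal(classify_pib(c(1.2, NA, 1.6), 1.41),
               c("negative", NA, "positive"))
  expect_error(classify_pib(1.5, -1))
})

test_that("positives split at their median, median itself going low", {
  s <- split_high_low(c(1.5, 1.9))
  expect_equal(s$low, 1L); expect_equal(s$high, 2L)

  x <- c(1.5, 1.6, 1.7, 1.8, 2.0, 2.2)  # median 1.75
  s2 <- split_high_low(x)
  expect_equal(x[s2$low], c(1.5, 1.6, 1.7))
  expect_equal(x[s2$high], c(1.8, 2.0, 2.2))

  expect_warning(s3 <- split_high_low(rep(1.6, 4)), "empty")
  expect_length(s3$high, 0)
  expect_length(s3$low, 4)
})

test_that("the mixture-based cluster alternative agrees on clear bimodality", {
  set.seed(41)
  x <- c(rnorm(46, 1.26, 0.07), rnorm(20, 1.9, 0.15))
  mcm <- main_cluster(x, method = "mixture")
  # the low component should be essentially the first 46
  expect_gt(length(mcm$cluster), 40)
  expect_lt(max(mcm$cluster), 1.7)
  expect_gt(min(mcm$outliers), 1.5)
})
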