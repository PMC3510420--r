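# frame integration, cerebellar scaling, regional retention

test_that("frame integration keeps only frames fully inside 40-60 min", {
  at <- tiny_atlas()
  mk_frames <- function(schedule, value = 2.5) {
    structure(list(
      frames = lapply(seq_len(nrow(schedule)), function(i)
        pet_volume(rep(value, prod(at$dim)), at$dim, at$vox_mm)),
      timing = schedule, centre = "X", fov_z = c(0, 1),
      dim = at$dim, vox_mm = at$vox_mm), class = "pet_frames")
  }
  # four 5-min frames of constant v sum to 4v
  fr <- mk_frames(five_min_frames(40, 60))
  expect_true(all(integrate_frames(fr) == 10))

  # published centre-A schedule: six frames 40-70, exactly 4 contribute
  frA <- mk_frames(five_min_frames(40, 70))
  intA <- integrate_frames(frA)
  expect_equal(attr(intA, "n_frames"), 4)
  expect_true(all(intA == 10))

  # straddling frame is discarded by the containment rule
  fr2 <- mk_frames(rbind(c(40, 45), c(58, 63)))
  expect_equal(attr(integrate_frames(fr2), "n_frames"), 1)

  expect_error(integrate_frames(mk_frames(rbind(c(0, 5)))), "no frames")
})

test_that("cerebellar median follows the order-statistic oracle", {
  d <- c(2L, 2L, 1L)
  mask <- pet_volume(rep(1, 4), d, 1)
  expect_equal(cerebellar_median(pet_volume(c(1, 1, 1, 100), d, 1), mask), 1)
  expect_equal(cerebellar_median(pet_volume(c(1, 2, 3, 4), d, 1), mask), 2.5)
  expect_equal(cerebellar_median(pet_volume(rep(3.3, 4), d, 1), mask), 3.3)
  expect_error(cerebellar_median(pet_volume(rep(1, 4), d, 1), mask * 0), "empty")
})

test_that("the median is unmoved by a large minority of outlier voxels", {
  n <- 101
  vals <- rep(2, n)
  poison <- sample(n, 49)
  vals[poison] <- 1e9
  v <- pet_volume(vals, c(n, 1, 1), 1)
  mask <- pet_volume(rep(1, n), c(n, 1, 1), 1)
  expect_equal(cerebellar_median(v, mask), 2)
})

test_that("field-of-view exclusion uses a strict 25 % rule", {
  # 20 cerebellar voxels stacked along z, one per slice
  d <- c(1L, 1L, 20L)
  cereb <- seq_len(20)
  expect_equal(check_fov(cereb, c(0, 1), dim = d),
               list(fraction_outside = 0, excluded = FALSE))
  # exactly 25 % outside: retained
  r5 <- check_fov(cereb, c(5 / 20, 1), dim = d)
  expect_equal(r5$fraction_outside, 0.25)
  expect_false(r5$excluded)
  # 30 % outside: excluded
  r6 <- check_fov(cereb, c(6 / 20, 1), dim = d)
  expect_equal(r6$fraction_outside, 0.30)
  expect_true(r6$excluded)
})

test_that("ratio images scale to unit cerebellar median", {
  d <- c(3L, 3L, 3L)
  v <- pet_volume(rep(4.2, 27), d, 1)
  expect_true(all(ratio_image(v, 4.2) == 1))
  expect_error(ratio_image(v, 0), "positive")
  expect_error(ratio_image(v, -1), "positive")

  # noiseless phantom: every cerebellar voxel of the ratio image is 1
  at <- tiny_atlas()
  rset <- exact_roiset(at)
  fr <- render_phantom(flat_ratios(at, 1.8), ideal_centre(dose_scale = 1.7), at)
  integral <- integrate_frames(fr)
  ratio <- ratio_image(integral, cerebellar_median(integral, rset$cerebellum))
  expect_true(all(abs(ratio[rset$cerebellum] - 1) < 1e-12))
})

test_that("noiseless quantification recovers ground truth to 1e-10", {
  at <- tiny_atlas()
  rset <- exact_roiset(at)
  cfg <- small_config()
  co <- sample_cohort(cfg, seed = 8)
  for (i in c(1, 15, 30)) {
    r <- subject_ratios(co, i)
    fr <- render_phantom(r, ideal_centre(), at, seed = i)
    q <- quantify_subject(fr, rset)
    expect_lt(max(abs(q$regional - r[names(q$regional)])), 1e-10)
    expect_lt(abs(q$composite - co$true_composite[i]), 1e-10)
  }
})

test_that("all-ones ratio image gives unit regional values and composite", {
  at <- tiny_atlas()
  rset <- exact_roiset(at)
  ones <- pet_volume(rep(1, prod(at$dim)), at$dim, at$vox_mm)
  rm_ <- regional_means(ones, rset)
  expect_true(all(rm_$regional == 1))
  expect_equal(neocortical_composite(rm_$regional), 1)
})

test_that("neocortical composite is the unweighted constituent mean", {
  reg <- c(frontal_L = 1.2, frontal_R = 1.2, parietal_L = 1.5,
           parietal_R = 1.5, temporal_latbas_L = 1.8, temporal_latbas_R = 1.8)
  expect_equal(neocortical_composite(reg), 1.5)
  expect_equal(neocortical_composite(c(a = 1.2, b = 1.5, c = 1.8),
                                     neocortical = c("a", "b", "c")), 1.5)
  expect_equal(neocortical_composite(c(a = 1.4, b = 1.4), neocortical = c("a", "b")), 1.4)
  expect_error(neocortical_composite(reg[-1]), "missing")
  reg2 <- reg; reg2[1] <- NA
  expect_error(neocortical_composite(reg2), "missing")
})

test_that("partial-volume blur pulls cortical values toward their surround", {
  # without erosion, edge voxels mix with background/white matter, and the
  # bias grows with PSF width (checked on a raw, uneroded ROI set)
  at <- small_atlas()
  rset_raw <- exact_roiset(at, erode = 0L)
  r <- flat_ratios(at, 1.26)
  vals <- sapply(c(0, 6, 12), function(fwhm) {
    ctr <- centre_profile("t", fwhm, 0, 1, five_min_frames(40, 60))
    q <- quantify_subject(render_phantom(r, ctr, at), rset_raw)
    mean(q$regional[c("frontal_L", "frontal_R")])
  })
  expect_equal(vals[1], 1.26, tolerance = 1e-12)
  # in this phantom the frontal shell borders hotter white matter (1.8), so
  # uneroded values inflate, monotonically in FWHM (verified against the
  # dense-convolution oracle in test-volume.R)
  expect_gt(vals[2], vals[1])
  expect_gt(vals[3], vals[2])
  expect_lt(vals[3], 1.8)       # bounded by the hottest neighbouring tissue

  # erosion restores near-exact recovery at the same PSF
  rset_er <- exact_roiset(at, erode = 2L)
  ctr6 <- centre_profile("t", 6, 0, 1, five_min_frames(40, 60))
  q_er <- quantify_subject(render_phantom(r, ctr6, at), rset_er)
  expect_equal(mean(q_er$regional[c("frontal_L", "frontal_R")]), 1.26,
               tolerance = 0.005)
})

test_that("template averaging is voxelwise and grid-checked", {
  d <- c(4L, 4L, 2L)
  v <- pet_volume(runif(32), d, 2)
  expect_equal(build_template(list(v)), v)
  w <- pet_volume(2 - as.numeric(v), d, 2)
  expect_true(all(abs(build_template(list(v, w)) - 1) < 1e-12))
  bad <- pet_volume(rep(1, 16), c(4L, 4L, 1L), 2)
  expect_error(build_template(list(v, bad)), "grid")

  # noiseless phantoms all have unit cerebellar median, so does the template
  at <- tiny_atlas()
  rset <- exact_roiset(at)
  vols <- lapply(c(1.2, 1.6, 2.0), function(val) {
    fr <- render_phantom(flat_ratios(at, val), ideal_centre(), at)
    integral <- integrate_frames(fr)
    ratio_image(integral, cerebellar_median(integral, rset$cerebellum))
  })
  tm <- build_template(vols)
  expect_equal(cerebellar_median(tm, rset$cerebellum), 1, tolerance = 1e-12)
})
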