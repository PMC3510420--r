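# shared fixtures, all built in code

tiny_atlas <- function() build_atlas(c(24L, 24L, 18L), 8)

small_atlas <- function() build_atlas(c(32L, 32L, 24L), 6)

# aberration-free scanner: no blur, no noise, unit dose, 4 frames in-window
ideal_centre <- function(dose_scale = 1, fov_z = c(0, 1)) {
  centre_profile("ideal", psf_fwhm = 0, noise_sd_fraction = 0,
                 dose_scale = dose_scale,
                 frame_schedule = five_min_frames(40, 60), fov_z = fov_z)
}

# exact (unperturbed) ROI set for an atlas, optionally eroded
exact_roiset <- function(atlas, erode = 0L) {
  gm <- atlas_gm_indicator(atlas)
  if (erode > 0) gm <- erode_mask(gm, erode)
  intersect_atlas(gm, atlas)
}

# small config so pipeline-level tests stay fast
small_config <- function(...) {
  generator_config(group_sizes = c(control = 12, MCI = 16, AD = 20), ...)
}

# named true-ratio vector with every region at `value` except fixed tissues
flat_ratios <- function(atlas, value, cereb = 1, wm = 1.8) {
  r <- stats::setNames(rep(value, nrow(atlas$lut)), atlas$lut$name)
  r["cerebellum"] <- cereb
  r["white_matter"] <- wm
  r
}

# brute-force one-voxel 6-connected erosion, used as the independent oracle
naive_erode_once <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    ok <- TRUE
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      p <- c(x, y, z) + s
      if (any(p < 1) || any(p > d) || !mask[p[1], p[2], p[3]]) { ok <- FALSE; break }
    }
    out[x, y, z] <- ok
  }
  out
}

# brute-force dense 3-D convolution with a separable Gaussian kernel
naive_blur <- function(vol, fwhm_mm, vox) {
  k <- amypet:::gauss_kernel_1d(fwhm_mm, vox)
  r <- (length(k) - 1L) %/% 2L
  d <- dim(vol)
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    acc <- 0
    for (i in -r:r) for (j in -r:r) for (l in -r:r) {
      p <- c(x + i, y + j, z + l)
      if (any(p < 1) || any(p > d)) next
      acc <- acc + vol[p[1], p[2], p[3]] * k[i + r + 1] * k[j + r + 1] * k[l + r + 1]
    }
    out[x, y, z] <- acc
  }
  out
}

# explicit risk-set tabulation of the two-group log-rank statistic
naive_logrank_chisq <- function(ta, ea, tb, eb) {
  times <- c(ta, tb); events <- c(ea, eb)
  grp_a <- rep(c(TRUE, FALSE), c(length(ta), length(tb)))
  o_a <- e_a <- v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk); n_a <- sum(at_risk & grp_a)
    d <- sum(times == t & events == 1)
    d_a <- sum(times == t & events == 1 & grp_a)
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  (o_a - e_a)^2 / v
}

# multiset difference for numeric vectors
setdiff_vals <- function(x, y) {
  for (v in y) {
    i <- match(v, x)
    if (!is.na(i)) x <- x[-i]
  }
  x
}
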