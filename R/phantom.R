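# cache of blurred label-indicator bases, keyed by grid + PSF
.basis_cache <- new.env(parent = emptyenv())

# nvox x nlabel matrix of PSF-blurred label indicators (background excluded).
# Rendering a label-constant phantom is then a single matrix-vector product,
# exactly equal (by linearity of convolution) to blurring the label image.
blurred_label_basis <- function(atlas, psf_fwhm) {
  key <- paste(c(atlas$dim, atlas$vox_mm, psf_fwhm), collapse = "|")
  hit <- .basis_cache[[key]]
  if (!is.null(hit)) return(hit)
  ids <- atlas$lut$id
  basis <- matrix(0, prod(atlas$dim), length(ids),
                  dimnames = list(NULL, atlas$lut$name))
  for (j in seq_along(ids)) {
    ind <- pet_volume(as.numeric(atlas$labels == ids[j]), atlas$dim, atlas$vox_mm)
    basis[, j] <- as.numeric(gaussian_blur_3d(ind, psf_fwhm))
  }
  .basis_cache[[key]] <- basis
  basis
}

#' Render a multicentre PET phantom frame series for one subject
#'
#' Voxel signal is `dose_scale` times the subject's true retention ratio of
#' the enclosing atlas label (background 0), convolved with the centre's
#' Gaussian point spread function. Each frame is an independent rendering
#' of this static map plus zero-mean Gaussian noise with SD equal to
#' `noise_sd_fraction` times the local blurred signal. Axial slices outside
#' the centre's field of view are masked as `NA` (the template grid is
#' kept, so downstream masks stay aligned).
#'
#' @param ratios named numeric vector of true regional ratios covering every
#'   atlas label (names as in `atlas$lut$name`).
#' @param centre a [centre_profile()].
#' @param atlas a [build_atlas()] result.
#' @param seed integer seed for the frame noise.
#' @param window optional `(start, end)` minutes; when given, only frames
#'   fully inside the window are rendered (a compute shortcut for
#'   simulation studies — the integration window discards the rest anyway).
#' @return a `pet_frames` object: list of frame volumes plus timing, centre
#'   name, field of view and grid metadata.
#' @export
render_phantom <- function(ratios, centre, atlas, seed = 1L, window = NULL) {
  need <- atlas$lut$name
  if (!all(need %in% names(ratios))) {
    stop("missing true ratio for label(s): ",
         paste(setdiff(need, names(ratios)), collapse = ", "), call. = FALSE)
  }
  sched <- centre$frame_schedule
  if (!is.null(window)) {
    keep <- sched[, 1] >= window[1] - 1e-9 & sched[, 2] <= window[2] + 1e-9
    sched <- sched[keep, , drop = FALSE]
  }
  if (nrow(sched) == 0) stop("no frames to render", call. = FALSE)

  basis <- blurred_label_basis(atlas, centre$psf_fwhm)
  signal <- centre$dose_scale * as.numeric(basis %*% ratios[colnames(basis)])
  noisy_idx <- which(signal > 0)
  sd_local <- centre$noise_sd_fraction * signal[noisy_idx]

  nz <- atlas$dim[3]
  z_keep <- seq_len(nz) > centre$fov_z[1] * nz + 1e-9 &
    seq_len(nz) <= centre$fov_z[2] * nz + 1e-9
  out_fov <- rep(!z_keep, each = prod(atlas$dim[1:2]))

  frames <- with_seed(seed, {
    lapply(seq_len(nrow(sched)), function(i) {
      v <- signal
      if (centre$noise_sd_fraction > 0 && length(noisy_idx)) {
        v[noisy_idx] <- v[noisy_idx] + stats::rnorm(length(noisy_idx), 0, sd_local)
      }
      v[out_fov] <- NA_real_
      pet_volume(v, atlas$dim, atlas$vox_mm)
    })
  })
  structure(list(frames = frames, timing = sched, centre = centre$name,
                 fov_z = centre$fov_z, dim = atlas$dim, vox_mm = atlas$vox_mm),
            class = "pet_frames")
}

#' @export
print.pet_frames <- function(x, ...) {
  cat("pet_frames:", length(x$frames), "frames,",
      paste(x$dim, collapse = " x "), "voxels, centre", x$centre, "\n")
  invisible(x)
}

#' Render subject-specific grey-matter probability maps
#'
#' Emulates the tissue-class maps of template subjects: probability about
#' 0.9 inside the atlas grey-matter labels and about 0 outside, plus a
#' smooth subject-specific Gaussian random field (clipped to `[0, 1]`).
#'
#' @param n number of maps (the published mask used ten subjects).
#' @param atlas a [build_atlas()] result.
#' @param seed integer seed.
#' @param perturb_amp SD of the smooth perturbation field (0 gives maps
#'   exactly equal to 0.9 times the grey-matter indicator).
#' @param perturb_fwhm_mm smoothness of the perturbation field in mm.
#' @return list of probability volumes.
#' @export
render_gm_probability_maps <- function(n, atlas, seed = 1L,
                                       perturb_amp = 0.1, perturb_fwhm_mm = 12) {
  stopifnot(n >= 1)
  gm <- atlas_gm_indicator(atlas)
  base <- 0.9 * gm
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      v <- base
      if (perturb_amp > 0) {
        field <- pet_volume(stats::rnorm(prod(atlas$dim)), atlas$dim, atlas$vox_mm)
        field <- gaussian_blur_3d(field, perturb_fwhm_mm)
        field <- field * (perturb_amp / stats::sd(field))
        v <- base + field
      }
      v <- pmin(pmax(v, 0), 1)
      pet_volume(v, atlas$dim, atlas$vox_mm)
    })
  })
}

#' Extract the true-ratio vector of one cohort row
#'
#' @param cohort data.frame from [sample_cohort()].
#' @param i row index.
#' @return named numeric vector of regional ratios.
#' @export
subject_ratios <- function(cohort, i) {
  cols <- grep("^ratio_", names(cohort), value = TRUE)
  stats::setNames(as.numeric(cohort[i, cols]), sub("^ratio_", "", cols))
}
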