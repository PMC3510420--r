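#' Sum frames falling inside the integration window
#'
#' A frame contributes only if its `[start, end)` interval lies entirely
#' inside the window; partially overlapping frames are discarded. The
#' default 40-60 min window is the maximal acquisition period common to
#' all centres.
#'
#' @param frames a `pet_frames` object from [render_phantom()].
#' @param window `(start, end)` minutes.
#' @return integral volume (voxelwise sum of the eligible frames).
#' @export
integrate_frames <- function(frames, window = c(40, 60)) {
  eps <- 1e-9
  keep <- frames$timing[, 1] >= window[1] - eps &
    frames$timing[, 2] <= window[2] + eps
  if (!any(keep)) stop("no frames fully inside the integration window", call. = FALSE)
  acc <- frames$frames[[which(keep)[1]]]
  for (i in which(keep)[-1]) acc <- acc + frames$frames[[i]]
  attr(acc, "vox_mm") <- frames$vox_mm
  attr(acc, "n_frames") <- sum(keep)
  acc
}

#' Median retention in the cerebellar reference region
#'
#' The median (not the mean) is used because the lowermost cerebellar
#' slices can carry high voxel variability; the median is insensitive to
#' such outliers. Even-count medians are the mean of the two central order
#' statistics. Out-of-field-of-view voxels (`NA`) are ignored.
#'
#' @param vol integral volume.
#' @param cerebellum binary volume or voxel-index vector of the reference
#'   region.
#' @return scalar median.
#' @export
cerebellar_median <- function(vol, cerebellum) {
  idx <- if (is.numeric(cerebellum) && is.null(dim(cerebellum))) {
    as.integer(cerebellum)
  } else {
    which(cerebellum > 0)
  }
  if (length(idx) == 0) stop("empty cerebellar reference region", call. = FALSE)
  vals <- vol[idx]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("cerebellar region entirely outside the field of view", call. = FALSE)
  stats::median(vals)
}

#' Field-of-view QC for the cerebellar reference region
#'
#' A subject is excluded when strictly more than `threshold` (default 25 %)
#' of the cerebellar reference voxels lie outside the axial field of view.
#'
#' @param cerebellum binary volume or voxel-index vector.
#' @param fov_z `(lo, hi)` fractions of the z-extent retained.
#' @param dim grid dimensions (required when `cerebellum` is an index vector).
#' @param threshold exclusion fraction, strict inequality.
#' @return list with `fraction_outside` and `excluded`.
#' @export
check_fov <- function(cerebellum, fov_z, dim = NULL, threshold = 0.25) {
  if (is.numeric(cerebellum) && is.null(base::dim(cerebellum))) {
    stopifnot(!is.null(dim))
    idx <- as.integer(cerebellum)
  } else {
    dim <- base::dim(cerebellum)
    idx <- which(cerebellum > 0)
  }
  if (length(idx) == 0) return(list(fraction_outside = 0, excluded = FALSE))
  nz <- dim[3]
  z <- ((idx - 1L) %/% prod(dim[1:2])) + 1L
  inside <- z > fov_z[1] * nz + 1e-9 & z <= fov_z[2] * nz + 1e-9
  frac <- 1 - mean(inside)
  list(fraction_outside = frac, excluded = frac > threshold)
}

#' Scale an integral image by its cerebellar median
#'
#' @param vol integral volume.
#' @param cereb_median positive scalar from [cerebellar_median()].
#' @return retention-ratio volume; the scaled cerebellar median is 1 by
#'   construction.
#' @export
ratio_image <- function(vol, cereb_median) {
  if (!is.finite(cereb_median) || cereb_median <= 0)
    stop("cerebellar median must be positive", call. = FALSE)
  out <- vol / cereb_median
  attr(out, "vox_mm") <- vox_mm(vol)
  out
}

#' Mean retention ratio per region of interest
#'
#' Arithmetic mean of the ratio-image voxels under each ROI (the median is
#' reserved for the cerebellar reference). Empty regions yield `NA` and
#' are reported in `missing`.
#'
#' @param ratio retention-ratio volume.
#' @param roiset a `roi_set` from [intersect_atlas()].
#' @return list with `regional` (named vector), `missing` (names).
#' @export
regional_means <- function(ratio, roiset) {
  vals <- vapply(roiset$rois, function(idx) {
    if (length(idx) == 0) return(NA_real_)
    v <- ratio[idx]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  list(regional = vals, missing = names(vals)[is.na(vals)])
}

#' Neocortical composite retention
#'
#' Unweighted mean of the frontal, parietal and lateral/basal temporal
#' ROI values — the study's primary readout.
#'
#' @param regional named numeric vector of regional values.
#' @param neocortical names of the constituent regions.
#' @return scalar composite.
#' @export
neocortical_composite <- function(regional,
                                  neocortical = c("frontal_L", "frontal_R",
                                                  "parietal_L", "parietal_R",
                                                  "temporal_latbas_L",
                                                  "temporal_latbas_R")) {
  if (!all(neocortical %in% names(regional)) ||
      anyNA(regional[neocortical]))
    stop("missing neocortical constituent region value", call. = FALSE)
  mean(regional[neocortical])
}

#' Average scaled images into a sample-based template
#'
#' @param ratio_volumes list of retention-ratio volumes on one grid.
#' @return voxelwise mean volume (out-of-FOV `NA`s ignored per voxel).
#' @export
build_template <- function(ratio_volumes) {
  stopifnot(length(ratio_volumes) >= 1)
  acc <- ratio_volumes[[1]]
  cnt <- !is.na(acc)
  acc[is.na(acc)] <- 0
  for (v in ratio_volumes[-1]) {
    stop_if_grid_mismatch(ratio_volumes[[1]], v)
    ok <- !is.na(v)
    v[!ok] <- 0
    acc <- acc + v
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  attr(out, "vox_mm") <- vox_mm(ratio_volumes[[1]])
  out
}

#' Quantify one subject's frame series
#'
#' Runs the full per-subject chain: 40-60 min frame integration,
#' field-of-view QC against the cerebellar reference, cerebellar-median
#' scaling, regional means and the neocortical composite.
#'
#' @param frames a `pet_frames`.
#' @param roiset a `roi_set`.
#' @param window integration window in minutes.
#' @param subject_id optional identifier carried through.
#' @param fov_threshold cerebellar out-of-FOV exclusion fraction.
#' @return a `regional_retention` list: `subject_id`, `centre`,
#'   `cereb_median`, `regional`, `composite`, `qc_excluded`, `qc_reason`,
#'   `fov_fraction_outside`, `missing_rois`.
#' @export
quantify_subject <- function(frames, roiset, window = c(40, 60),
                             subject_id = NA_character_, fov_threshold = 0.25) {
  fov <- check_fov(roiset$cerebellum, frames$fov_z, dim = frames$dim,
                   threshold = fov_threshold)
  if (fov$excluded) {
    return(structure(list(subject_id = subject_id, centre = frames$centre,
                          cereb_median = NA_real_, regional = NULL,
                          composite = NA_real_, qc_excluded = TRUE,
                          qc_reason = "fov",
                          fov_fraction_outside = fov$fraction_outside,
                          missing_rois = character()),
                     class = "regional_retention"))
  }
  integral <- integrate_frames(frames, window)
  cm <- cerebellar_median(integral, roiset$cerebellum)
  ratio <- ratio_image(integral, cm)
  rm_ <- regional_means(ratio, roiset)
  composite <- tryCatch(
    neocortical_composite(rm_$regional, roiset$neocortical),
    error = function(e) NA_real_)
  structure(list(subject_id = subject_id, centre = frames$centre,
                 cereb_median = cm, regional = rm_$regional,
                 composite = composite, qc_excluded = FALSE,
                 qc_reason = NA_character_,
                 fov_fraction_outside = fov$fraction_outside,
                 missing_rois = rm_$missing),
            class = "regional_retention")
}

#' @export
print.regional_retention <- function(x, ...) {
  cat("regional_retention:", x$subject_id, "centre", x$centre,
      if (x$qc_excluded) paste("EXCLUDED (", x$qc_reason, ")") else
        sprintf("composite %.3f (cereb median %.3f)", x$composite, x$cereb_median),
      "\n")
  invisible(x)
}
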