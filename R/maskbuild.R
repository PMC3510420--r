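#' Binarized grey-matter mask from probability maps
#'
#' Sums the subject tissue-probability maps and thresholds at 50 %:
#' a voxel is included iff its mean grey-matter probability across maps is
#' at least 0.5 (inclusive at the boundary; equivalently the summed maps
#' reach half the number of maps).
#'
#' @param prob_maps list of probability volumes on one grid, values in `[0, 1]`.
#' @return binary volume (0/1).
#' @export
build_gm_mask <- function(prob_maps) {
  stopifnot(length(prob_maps) >= 1)
  acc <- prob_maps[[1]]
  rng <- range(vapply(prob_maps, function(m) range(m), numeric(2)))
  if (rng[1] < 0 || rng[2] > 1) stop("probability maps must lie in [0, 1]", call. = FALSE)
  if (length(prob_maps) > 1) {
    for (m in prob_maps[-1]) {
      stop_if_grid_mismatch(acc, m)
      acc <- acc + m
    }
  }
  # small tolerance so exact-0.5 means survive floating accumulation error
  mask <- (acc / length(prob_maps)) >= 0.5 - 1e-9
  if (!any(mask)) stop("QC: grey-matter mask is empty", call. = FALSE)
  out <- array(as.numeric(mask), dim = dim(acc))
  attr(out, "vox_mm") <- vox_mm(prob_maps[[1]])
  out
}

# shift a 3-D array by one voxel along axis, padding with `fill`
shift1 <- function(a, axis, step, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (step == 1) {
    src[[axis]] <- seq_len(d[axis] - 1L); dst[[axis]] <- 2:d[axis]
  } else {
    src[[axis]] <- 2:d[axis]; dst[[axis]] <- seq_len(d[axis] - 1L)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Binary erosion of a mask
#'
#' Default is iterated one-voxel erosion with the 6-connected
#' (face-neighbour) structuring element; outside the grid counts as
#' background. `method = "box"` instead applies a single pass with a cubic
#' `(2*iterations+1)^3` element ("two voxels in all dimensions" read as a
#' box), exposed for sensitivity analysis.
#'
#' @param mask binary volume.
#' @param iterations non-negative erosion depth in voxels.
#' @param method `"face"` (default) or `"box"`.
#' @return binary volume, a subset of the input. May be empty.
#' @export
erode_mask <- function(mask, iterations = 2L, method = c("face", "box")) {
  method <- match.arg(method)
  stopifnot(iterations >= 0)
  if (iterations == 0) return(mask)
  m <- mask > 0
  if (method == "face") {
    for (it in seq_len(iterations)) {
      m <- m &
        shift1(m, 1, 1, FALSE) & shift1(m, 1, -1, FALSE) &
        shift1(m, 2, 1, FALSE) & shift1(m, 2, -1, FALSE) &
        shift1(m, 3, 1, FALSE) & shift1(m, 3, -1, FALSE)
    }
  } else {
    r <- as.integer(iterations)
    for (axis in 1:3) {
      acc <- m
      cur_p <- m; cur_n <- m
      for (s in seq_len(r)) {
        cur_p <- shift1(cur_p, axis, 1, FALSE)
        cur_n <- shift1(cur_n, axis, -1, FALSE)
        acc <- acc & cur_p & cur_n
      }
      m <- acc
    }
  }
  out <- array(as.numeric(m), dim = dim(mask))
  attr(out, "vox_mm") <- vox_mm(mask)
  out
}

#' Intersect an eroded grey-matter mask with the label atlas
#'
#' Produces the working ROI set: each of the 23 grey-matter regions is the
#' atlas label restricted to the mask, and the cerebellar reference region
#' is handled identically. Empty regions are flagged; if every region is
#' empty a QC error is raised.
#'
#' @param gm_mask binary volume (typically [build_gm_mask()] then
#'   [erode_mask()]).
#' @param atlas a [build_atlas()] result.
#' @return a `roi_set`: named list of voxel-index vectors (`rois`), the
#'   cerebellar index vector (`cerebellum`), the mask, names of empty
#'   regions, the neocortical composite region names, and grid metadata.
#' @export
intersect_atlas <- function(gm_mask, atlas) {
  stopifnot(identical(dim(gm_mask), as.integer(atlas$dim)) ||
              identical(dim(gm_mask), atlas$dim))
  roi_names <- atlas_roi_names(atlas)
  ids <- atlas$lut$id[match(roi_names, atlas$lut$name)]
  inmask <- gm_mask > 0
  lab <- atlas$labels
  rois <- lapply(ids, function(id) which(lab == id & inmask))
  names(rois) <- roi_names
  cereb_id <- atlas$lut$id[atlas$lut$name == "cerebellum"]
  if (length(cereb_id) != 1 || !any(lab == cereb_id))
    stop("atlas is missing the cerebellar label", call. = FALSE)
  cereb <- which(lab == cereb_id & inmask)
  empty <- names(rois)[vapply(rois, length, 1L) == 0]
  if (length(empty) == length(rois) && length(cereb) == 0)
    stop("QC: all regions are empty after mask intersection", call. = FALSE)
  structure(list(rois = rois, cerebellum = cereb, gm_mask = gm_mask,
                 empty = empty, neocortical = atlas$neocortical,
                 dim = atlas$dim, vox_mm = atlas$vox_mm),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("roi_set:", length(x$rois), "ROIs (", length(x$empty), "empty ),",
      "cerebellum", length(x$cerebellum), "voxels\n")
  invisible(x)
}

#' Standard ROI-set construction from maps + atlas
#'
#' Convenience wrapper: threshold the probability maps at 50 %, erode by
#' two voxels, intersect with the atlas.
#'
#' @param prob_maps list of grey-matter probability volumes.
#' @param atlas a [build_atlas()] result.
#' @param erode_iterations erosion depth (default 2).
#' @param erode_method passed to [erode_mask()].
#' @return a `roi_set`.
#' @export
build_roi_set <- function(prob_maps, atlas, erode_iterations = 2L,
                          erode_method = "face") {
  gm <- build_gm_mask(prob_maps)
  gm <- erode_mask(gm, erode_iterations, erode_method)
  intersect_atlas(gm, atlas)
}
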