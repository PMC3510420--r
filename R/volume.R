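#' Create a template-space volume
#'
#' Volumes are plain 3-D numeric arrays carrying a `vox_mm` attribute
#' (isotropic voxel edge length in millimetres). All phantoms, masks and
#' atlases in the package live on one such grid, standing in for MNI space.
#'
#' @param data numeric vector or array of length `prod(dim)`.
#' @param dim integer length-3 grid dimensions.
#' @param vox_mm isotropic voxel size in mm.
#' @return a 3-D array with attribute `vox_mm`.
#' @export
pet_volume <- function(data, dim, vox_mm) {
  stopifnot(length(dim) == 3L, length(data) == prod(dim), vox_mm > 0)
  v <- array(as.numeric(data), dim = as.integer(dim))
  attr(v, "vox_mm") <- as.numeric(vox_mm)
  v
}

#' @rdname pet_volume
#' @param vol a volume.
#' @export
vox_mm <- function(vol) {
  v <- attr(vol, "vox_mm")
  if (is.null(v)) 1 else v
}

same_grid <- function(a, b) {
  identical(dim(a), dim(b)) && isTRUE(all.equal(vox_mm(a), vox_mm(b)))
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("volumes are not on a common voxel grid", call. = FALSE)
  invisible(TRUE)
}

#' One-dimensional Gaussian convolution kernel
#'
#' @param fwhm_mm full width at half maximum in mm; 0 gives the identity.
#' @param vox_mm voxel size in mm.
#' @return normalized kernel weights (odd length).
#' @keywords internal
gauss_kernel_1d <- function(fwhm_mm, vox_mm) {
  if (fwhm_mm <= 0) return(1)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox_mm # voxel units
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# convolve the first dimension of a matrix (columns are fibres), zero-padded
conv_cols <- function(mat, k) {
  if (length(k) == 1L) return(mat * k)
  n <- nrow(mat)
  r <- (length(k) - 1L) %/% 2L
  out <- matrix(0, n, ncol(mat))
  idx <- seq_len(n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- idx + off
    ok <- src >= 1L & src <= n
    out[idx[ok], ] <- out[idx[ok], ] + k[j] * mat[src[ok], , drop = FALSE]
  }
  out
}

#' Isotropic Gaussian blur of a 3-D volume
#'
#' Separable convolution with zero padding outside the grid; used as the
#' scanner point-spread-function model in phantom rendering.
#'
#' @param vol 3-D array with a `vox_mm` attribute.
#' @param fwhm_mm PSF full width at half maximum in mm (0 = no blur).
#' @return blurred volume on the same grid.
#' @export
gaussian_blur_3d <- function(vol, fwhm_mm) {
  if (fwhm_mm <= 0) return(vol)
  d <- dim(vol)
  k <- gauss_kernel_1d(fwhm_mm, vox_mm(vol))
  x <- conv_cols(matrix(vol, d[1]), k)                       # along x
  x <- array(x, d)
  x <- aperm(array(conv_cols(matrix(aperm(x, c(2, 1, 3)), d[2]), k),
                   d[c(2, 1, 3)]), c(2, 1, 3))               # along y
  x <- aperm(array(conv_cols(matrix(aperm(x, c(3, 1, 2)), d[3]), k),
                   d[c(3, 1, 2)]), c(2, 3, 1))               # along z
  attr(x, "vox_mm") <- vox_mm(vol)
  x
}
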