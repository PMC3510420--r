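#' Minimal NIfTI-1 volume I/O
#'
#' Writes/reads single-frame 3-D float32 NIfTI-1 files (`.nii` or `.nii.gz`),
#' little-endian, enough to exchange phantoms, masks and atlases with
#' standard neuroimaging tools. No installed R package provides NIfTI in
#' this stack, so the 348-byte header is emitted directly.
#'
#' @param vol 3-D array with a `vox_mm` attribute.
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(length(dim(vol)) == 3L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                       # sizeof_hdr
  w_raw(36L)                        # data_type..dim_info
  w_i16(c(3L, dim(vol), 1L, 1L, 1L, 1L))  # dim[8]
  w_f32(c(0, 0, 0))                 # intent_p1..p3
  w_i16(0L)                         # intent_code
  w_i16(16L)                        # datatype = float32
  w_i16(32L)                        # bitpix
  w_i16(0L)                         # slice_start
  w_f32(c(1, rep(vox_mm(vol), 3), 0, 0, 0, 0))  # pixdim[8]
  w_f32(352)                        # vox_offset
  w_f32(c(1, 0))                    # scl_slope, scl_inter
  w_i16(0L); w_raw(1L); w_raw(1L)   # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0))                 # cal_max, cal_min, slice_duration
  w_f32(0)                          # toffset
  w_i32(c(0L, 0L))                  # glmax, glmin
  w_raw(80L); w_raw(24L)            # descrip, aux_file
  w_i16(c(0L, 1L))                  # qform_code, sform_code = aligned
  w_f32(c(0, 0, 0, 0, 0, 0))        # quatern b,c,d + qoffset x,y,z
  v <- vox_mm(vol)
  w_f32(c(v, 0, 0, 0))              # srow_x
  w_f32(c(0, v, 0, 0))              # srow_y
  w_f32(c(0, 0, v, 0))              # srow_z
  w_raw(16L)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  w_raw(4L)                         # extension flag
  w_f32(as.numeric(vol))
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  r_i32 <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  r_i16 <- function(n) readBin(con, "integer", n, size = 2L, endian = "little")
  r_f32 <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  if (r_i32(1L) != 348L) stop("not a little-endian NIfTI-1 file", call. = FALSE)
  readBin(con, "raw", 36L)
  dm <- r_i16(8L)
  if (dm[1] != 3L) stop("only 3-D volumes supported", call. = FALSE)
  r_f32(3L); r_i16(1L)
  datatype <- r_i16(1L)
  if (datatype != 16L) stop("only float32 NIfTI supported", call. = FALSE)
  r_i16(2L)
  pixdim <- r_f32(8L)
  vox_offset <- r_f32(1L)
  slope <- r_f32(1L); inter <- r_f32(1L)
  # skip remainder of the header + extension flag
  readBin(con, "raw", vox_offset - 120L)
  n <- prod(dm[2:4])
  data <- r_f32(n)
  if (slope != 0 && slope != 1) data <- data * slope + inter
  pet_volume(data, dm[2:4], pixdim[2])
}
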