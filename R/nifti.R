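# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# The pipeline's external interface stores volumes and masks as NIfTI; no
# NIfTI package is available in the target environment, so a self-contained
# reader/writer for the small subset we need (3-D arrays, uint8/int16/
# float32/float64, little-endian, no extensions) lives here.

.nifti_dtypes <- list(`2` = "uint8", `4` = "int16", `16` = "float32", `64` = "float64")

#' Write a 3-D array as a NIfTI-1 file
#'
#' @param a numeric or logical 3-D array
#' @param path output path; gzip-compressed when it ends in `.gz`
#' @param spacing voxel spacing in mm per axis (length 3)
#' @param datatype one of `"uint8"`, `"int16"`, `"float32"`, `"float64"`;
#'   default stores logical arrays as uint8 and numeric as float32
#' @return `path`, invisibly
#' @export
nifti_write <- function(a, path, spacing = c(1, 1, 1), datatype = NULL) {
  stopifnot(length(dim(a)) == 3L, length(spacing) == 3L, all(spacing > 0))
  if (is.null(datatype)) datatype <- if (is.logical(a)) "uint8" else "float32"
  code <- switch(datatype, uint8 = 2L, int16 = 4L, float32 = 16L, float64 = 64L,
                 stop("unsupported datatype: ", datatype))
  bitpix <- switch(datatype, uint8 = 8L, int16 = 16L, float32 = 32L, float64 = 64L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                         # sizeof_hdr
  w_raw(36L)                          # data_type..dim_info
  w_i16(c(3L, dim(a), 1L, 1L, 1L, 1L))  # dim[8]
  w_raw(14L)                          # intent_p1..intent_code
  w_i16(code); w_i16(bitpix)          # datatype, bitpix
  w_i16(0L)                           # slice_start
  w_f32(c(1, spacing, 1, 1, 1, 1))    # pixdim[8]
  w_f32(352)                          # vox_offset
  w_f32(1); w_f32(0)                  # scl_slope, scl_inter
  w_raw(2L + 1L + 1L)                 # slice_end, slice_code, xyzt_units
  w_f32(0); w_f32(0); w_f32(0)        # cal_max, cal_min, slice_duration
  w_f32(0)                            # toffset
  w_i32(0L); w_i32(0L)                # glmax, glmin
  w_raw(80L + 24L)                    # descrip, aux_file
  w_i16(0L); w_i16(1L)                # qform_code, sform_code = 1 (scaled id)
  w_f32(rep(0, 6))                    # quatern b,c,d + qoffset x,y,z
  w_f32(c(spacing[1], 0, 0, 0))       # srow_x
  w_f32(c(0, spacing[2], 0, 0))       # srow_y
  w_f32(c(0, 0, spacing[3], 0))       # srow_z
  w_raw(16L)                          # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  w_raw(4L)                           # extension flag

  v <- as.vector(a)
  if (datatype %in% c("uint8", "int16")) {
    writeBin(as.integer(round(v)), con, size = bitpix / 8L, endian = "little")
  } else {
    writeBin(as.double(v), con, size = bitpix / 8L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by [nifti_write()] (or any plain
#' little-endian single-file NIfTI-1 volume)
#'
#' @param path `.nii` or `.nii.gz` path
#' @return 3-D array with attribute `spacing` (mm per axis)
#' @export
nifti_read <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  r_i32 <- function(off) readBin(hdr[off + 1:4], "integer", size = 4L, endian = "little")
  r_i16 <- function(off, n = 1L) readBin(hdr[off + seq_len(2L * n)], "integer",
                                         size = 2L, n = n, endian = "little")
  r_f32 <- function(off, n = 1L) readBin(hdr[off + seq_len(4L * n)], "double",
                                         size = 4L, n = n, endian = "little")
  if (r_i32(0) != 348L) stop("not a little-endian NIfTI-1 file")
  dims <- r_i16(40, 8L)
  if (dims[1] < 3L) stop("expected a 3-D volume")
  d <- dims[2:4]
  code <- r_i16(70)
  dt <- .nifti_dtypes[[as.character(code)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", code)
  spacing <- r_f32(76, 8L)[2:4]
  vox_offset <- r_f32(108)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  v <- switch(dt,
    uint8  = as.double(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    int16  = as.double(readBin(con, "integer", n, size = 2L, endian = "little")),
    float32 = readBin(con, "double", n, size = 4L, endian = "little"),
    float64 = readBin(con, "double", n, size = 8L, endian = "little"))
  slope <- r_f32(112); inter <- r_f32(116)
  if (slope != 0 && !(slope == 1 && inter == 0)) v <- v * slope + inter
  a <- array(v, dim = d)
  attr(a, "spacing") <- spacing
  a
}
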