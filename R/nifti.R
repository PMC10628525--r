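#' Minimal NIfTI-1 input/output
#'
#' Reads and writes single-file NIfTI-1 (`.nii`, `.nii.gz`) volumes with
#' voxel spacing carried in `pixdim` and origin in the sform translation.
#' Only the subset of the format the pipeline needs is supported: 3D
#' images, datatypes uint8 / int16 / int32 / float32 / float64, scalar
#' `scl_slope`/`scl_inter` rescaling on read, little- or big-endian files.
#' This keeps the package self-contained where no NIfTI reader is
#' otherwise available.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `nifti_read()` returns an [image_volume()].
#' @name nifti_io
NULL

.nifti_datatypes <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

.nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' @param x an [image_volume()], [roi_mask()] or 3D array.
#' @param spacing voxel spacing (mm); taken from `x` when it carries one.
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`. Masks default to `"uint8"`, volumes to `"float32"`.
#' @rdname nifti_io
#' @export
nifti_write <- function(x, path, spacing = NULL, datatype = NULL) {
  if (inherits(x, "roi_mask")) {
    if (is.null(datatype)) datatype <- "uint8"
    if (is.null(spacing)) spacing <- x$spacing
    arr <- x$data
    origin <- c(0, 0, 0)
  } else if (inherits(x, "image_volume")) {
    if (is.null(datatype)) datatype <- "float32"
    if (is.null(spacing)) spacing <- x$spacing
    arr <- x$data
    origin <- x$origin
  } else {
    if (is.null(datatype)) datatype <- "float32"
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    arr <- x
    origin <- c(0, 0, 0)
  }
  if (length(dim(arr)) != 3L) stop("only 3D volumes are supported")
  dt <- .nifti_datatypes[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)

  con <- .nifti_con(path, "wb")
  on.exit(close(con))
  w_i32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w_f32 <- function(v) writeBin(as.double(v), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_chr <- function(s, n) {
    b <- charToRaw(s)
    writeBin(c(b, raw(n - length(b))), con)
  }

  w_i32(348L)                      # sizeof_hdr
  w_raw(10L); w_raw(18L)           # data_type, db_name (unused)
  w_i32(0L); w_i16(0L)             # extents, session_error
  w_raw(1L); w_raw(1L)             # regular, dim_info
  w_i16(c(3L, dim(arr), 1L, 1L, 1L, 1L))       # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)     # intent_p1..3, intent_code
  w_i16(dt$code); w_i16(dt$bitpix); w_i16(0L)  # datatype, bitpix, slice_start
  w_f32(c(1, spacing, 1, 1, 1, 1)) # pixdim[8]
  w_f32(352)                       # vox_offset
  w_f32(1); w_f32(0)               # scl_slope, scl_inter
  w_i16(0L); w_raw(1L)             # slice_end, slice_code
  writeBin(as.raw(2L), con)        # xyzt_units: mm
  w_f32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                 # glmax, glmin
  w_chr("deltaradiomics", 80L)     # descrip
  w_raw(24L)                       # aux_file
  w_i16(0L); w_i16(1L)             # qform_code, sform_code
  w_f32(c(0, 0, 0)); w_f32(c(0, 0, 0))  # quatern, qoffset
  w_f32(c(spacing[1], 0, 0, origin[1])) # srow_x
  w_f32(c(0, spacing[2], 0, origin[2])) # srow_y
  w_f32(c(0, 0, spacing[3], origin[3])) # srow_z
  w_raw(16L)                       # intent_name
  w_chr("n+1", 4L)                 # magic
  w_raw(4L)                        # extension flag

  if (dt$what == "integer") {
    writeBin(as.integer(arr), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(arr), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' @rdname nifti_io
#' @export
nifti_read <- function(path) {
  con <- .nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  rd <- function(off, what, n, size, endian, signed = TRUE)
    readBin(hdr[(off + 1L):length(hdr)], what, n = n, size = size,
            endian = endian, signed = signed)
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L, "little") != 348L) {
    if (rd(0L, "integer", 1L, 4L, "big") == 348L) endian <- "big"
    else stop("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unrecognized NIfTI magic in ", path)
  dims <- rd(40L, "integer", 8L, 2L, endian)
  ndim <- dims[1L]
  if (ndim < 3L) stop("expected a 3D volume in ", path)
  shape <- dims[2:4]
  if (ndim > 3L && any(dims[5:(1L + ndim)] > 1L))
    stop("only single-frame 3D volumes are supported: ", path)
  dtcode <- rd(70L, "integer", 1L, 2L, endian)
  dt_i <- which(vapply(.nifti_datatypes, function(d) d$code == dtcode, logical(1)))
  if (length(dt_i) != 1L) stop("unsupported NIfTI datatype code ", dtcode)
  dt <- .nifti_datatypes[[dt_i]]
  pixdim <- rd(76L, "double", 8L, 4L, endian)
  vox_offset <- rd(108L, "double", 1L, 4L, endian)
  scl_slope <- rd(112L, "double", 1L, 4L, endian)
  scl_inter <- rd(116L, "double", 1L, 4L, endian)
  sform_code <- rd(254L, "integer", 1L, 2L, endian)
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    srow <- rbind(rd(280L, "double", 4L, 4L, endian),
                  rd(296L, "double", 4L, 4L, endian),
                  rd(312L, "double", 4L, 4L, endian))
    origin <- srow[, 4L]
  }
  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(shape)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  image_volume(array(vals, dim = shape), spacing = abs(pixdim[2:4]),
               origin = origin)
}
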