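# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only the subset of the format needed for binary masks and statistic maps is
# supported: 3-D volumes, sform affine, datatypes uint8/int16/int32/float32/
# float64, optional scl_slope/scl_inter rescaling, both endiannesses on read.

NIFTI_DATATYPES <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

nifti_datatype_by_code <- function(code) {
  for (nm in names(NIFTI_DATATYPES)) {
    if (NIFTI_DATATYPES[[nm]]$code == code) {
      return(c(NIFTI_DATATYPES[[nm]], list(name = nm)))
    }
  }
  stop("unsupported NIfTI datatype code: ", code)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 volume (`.nii`, gzip-compressed or not) into an
#' R array together with its voxel-to-world affine. Only 3-D volumes are
#' returned (trailing singleton dimensions are dropped). The sform affine is
#' preferred; if absent, a diagonal affine built from `pixdim` is used.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array), `affine` (4x4 matrix),
#'   and `pixdim` (voxel dimensions in mm, length 3).
#' @seealso [write_nifti()], [read_mask()]
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))

  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    sz_swapped <- readBin(writeBin(sizeof_hdr, raw(), size = 4L, endian = "big"),
                          "integer", 1L, size = 4L, endian = "little")
    if (sz_swapped == 348L) {
      endian <- "big"
    } else {
      stop("not a NIfTI-1 file (sizeof_hdr = ", sizeof_hdr, "): ", path)
    }
  }

  readBin(con, "raw", 36L)                                   # unused fields up to dim
  dim <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                                   # intent_p1..intent_code
  datatype_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 132L)                                  # slice_end .. aux_file
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # qform_code
  sform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "numeric", 6L, size = 4L, endian = endian)    # quaternion fields
  srow <- matrix(readBin(con, "numeric", 12L, size = 4L, endian = endian),
                 nrow = 3L, byrow = TRUE)
  readBin(con, "raw", 16L)                                   # intent_name
  magic <- readBin(con, "raw", 4L)
  magic_str <- rawToChar(magic[magic != as.raw(0)])
  if (!magic_str %in% c("n+1", "ni1")) {
    stop("missing NIfTI magic string in ", path)
  }

  ndim <- dim[1L]
  if (ndim < 1L || ndim > 7L) stop("invalid dim[0] = ", ndim, " in ", path)
  shape <- dim[seq(2L, 1L + ndim)]
  if (any(shape < 1L)) stop("invalid dimensions in ", path)
  if (prod(shape[-seq_len(min(3L, ndim))]) != 1L) {
    stop("only 3-D volumes are supported: ", path)
  }
  shape3 <- c(shape, 1L, 1L)[1:3]

  dt <- nifti_datatype_by_code(datatype_code)
  n_vox <- prod(shape3)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  vals <- readBin(con, dt$what, n_vox, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n_vox) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }

  affine <- rbind(srow, c(0, 0, 0, 1))
  if (sform_code <= 0L || all(srow == 0)) {
    affine <- diag(c(pixdim[2:4], 1))
  }
  list(data = array(as.numeric(vals), dim = shape3),
       affine = affine,
       pixdim = abs(pixdim[2:4]))
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3-D array as a single-file NIfTI-1 volume with the given
#' voxel-to-world affine stored in the sform (sform_code = 2, aligned). Paths
#' ending in `.gz` are gzip-compressed. `NA` values are stored as `NaN`
#' (float datatypes only).
#'
#' @param vol 3-D numeric, integer or logical array.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype One of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, affine, path, datatype = "float32") {
  if (length(dim(vol)) != 3L) stop("`vol` must be a 3-D array")
  if (!is.matrix(affine) || any(dim(affine) != 4L)) stop("`affine` must be 4x4")
  dt <- NIFTI_DATATYPES[[match.arg(datatype, names(NIFTI_DATATYPES))]]
  if (dt$what == "integer" && anyNA(vol)) {
    stop("NA values require a float datatype")
  }

  shape <- dim(vol)
  pixdim3 <- sqrt(colSums(affine[1:3, 1:3]^2))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f4 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i4(348L)                                   # sizeof_hdr
  w_raw(36L)                                   # data_type, db_name, extents, ...
  w_i2(c(3L, shape, 1L, 1L, 1L, 1L))           # dim
  w_raw(12L)                                   # intent_p1..p3
  w_i2(0L)                                     # intent_code
  w_i2(dt$code)                                # datatype
  w_i2(dt$bitpix)                              # bitpix
  w_i2(0L)                                     # slice_start
  w_f4(c(1, pixdim3, 1, 1, 1, 1))              # pixdim
  w_f4(352)                                    # vox_offset
  w_f4(1)                                      # scl_slope
  w_f4(0)                                      # scl_inter
  w_i2(0L); w_raw(2L)                          # slice_end, slice_code, xyzt_units
  w_f4(c(0, 0, 0, 0))                          # cal_max, cal_min, slice_duration, toffset
  w_i4(c(0L, 0L))                              # glmax, glmin
  w_raw(104L)                                  # descrip, aux_file
  w_i2(0L)                                     # qform_code
  w_i2(2L)                                     # sform_code (aligned)
  w_f4(rep(0, 6))                              # quaternion fields
  w_f4(t(affine[1:3, , drop = FALSE]))         # srow_x, srow_y, srow_z
  w_raw(16L)                                   # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  w_raw(4L)                                    # extension indicator

  vals <- as.vector(vol)
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
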