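# Minimal NIfTI-1 (.nii, single-file, uncompressed) I/O.
#
# The installed stack has no R NIfTI package, and this pipeline needs only a
# small, well-defined subset of the format: 3-D/4-D arrays, voxel spacings,
# and a handful of numeric datatypes. Reader handles both endiannesses
# (detected from sizeof_hdr) and applies scl_slope/scl_inter; writer emits
# little-endian files with data at offset 352 and no extensions.

NIFTI_DATATYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, mode = "integer"), # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  mode = "integer"), # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  mode = "integer"), # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE,  mode = "double"),  # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE,  mode = "double")   # float64
)

#' Read a NIfTI-1 volume
#'
#' Reads an uncompressed single-file NIfTI-1 image (`.nii`). Supports uint8,
#' int16, int32, float32 and float64 data, either endianness, and applies the
#' header's intensity scaling (`scl_slope`, `scl_inter`) when set.
#'
#' @param path Path to a `.nii` file.
#' @return A list with `data` (numeric array, dims as stored), `pixdim`
#'   (numeric vector of grid spacings, mm, one per dimension) and `datatype`
#'   (NIfTI datatype code).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("NIfTI file not found: ", path), class = "strokevol_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  sizeof_hdr <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  endian <- "little"
  if (sizeof_hdr != 348L) {
    swapped <- readBin(writeBin(sizeof_hdr, raw()), "integer",
                       n = 1L, size = 4L, endian = "swap")
    if (swapped == 348L) {
      endian <- "big"
    } else {
      abort(paste0("Not a NIfTI-1 file (sizeof_hdr = ", sizeof_hdr, "): ", path),
            class = "strokevol_format_error")
    }
  }
  seek(con, 40L)
  dim_field <- readBin(con, "integer", n = 8L, size = 2L, endian = endian)
  seek(con, 70L)
  datatype <- readBin(con, "integer", n = 1L, size = 2L, endian = endian)
  seek(con, 76L)
  pixdim <- readBin(con, "double", n = 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", n = 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", n = 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", n = 1L, size = 4L, endian = endian)
  seek(con, 344L)
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(rawToChar(magic[1:3]), "n+1")) {
    abort(paste0("Unsupported NIfTI magic in ", path,
                 " (only single-file 'n+1' images are handled)."),
          class = "strokevol_format_error")
  }

  ndim <- dim_field[1L]
  if (ndim < 1L || ndim > 7L) {
    abort(paste0("Invalid NIfTI dim[0] = ", ndim), class = "strokevol_format_error")
  }
  dims <- dim_field[seq_len(ndim) + 1L]
  if (any(dims < 1L)) {
    abort("NIfTI header declares a non-positive dimension.",
          class = "strokevol_format_error")
  }
  dt <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(dt)) {
    abort(paste0("Unsupported NIfTI datatype code ", datatype),
          class = "strokevol_format_error")
  }

  n_vox <- prod(as.double(dims))
  seek(con, as.integer(vox_offset))
  values <- readBin(con, dt$what, n = n_vox, size = dt$size,
                    signed = dt$signed, endian = endian)
  if (length(values) != n_vox) {
    abort(paste0("Truncated NIfTI data in ", path), class = "strokevol_format_error")
  }
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    values <- values * scl_slope + scl_inter
  }
  data <- array(values, dim = dims)
  list(data = data, pixdim = pixdim[seq_len(ndim) + 1L], datatype = datatype)
}

#' Write a NIfTI-1 volume
#'
#' Writes a numeric array as an uncompressed little-endian single-file
#' NIfTI-1 image. Doubles are stored as float64 so write/read round trips are
#' bit-exact; integer arrays are stored as int32.
#'
#' @param data A 3-D or 4-D numeric array.
#' @param path Output path (`.nii`).
#' @param pixdim Grid spacing per dimension, mm (recycled/padded with 1).
#' @param datatype NIfTI datatype code: 64 (float64, default for doubles),
#'   16 (float32), 8 (int32, default for integer arrays), 4 (int16) or
#'   2 (uint8).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = NULL,
                        datatype = if (is.integer(data)) 8L else 64L) {
  dims <- dim(data)
  if (is.null(dims) || length(dims) < 2L || length(dims) > 7L) {
    abort("`data` must be an array with 2 to 7 dimensions.",
          class = "strokevol_io_error")
  }
  dt <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(dt)) {
    abort(paste0("Unsupported NIfTI datatype code ", datatype),
          class = "strokevol_io_error")
  }
  if (is.null(pixdim)) pixdim <- rep(1, length(dims))
  pixdim <- c(pixdim, rep(1, length(dims)))[seq_along(dims)]

  dim_field <- integer(8L)
  dim_field[1L] <- length(dims)
  dim_field[seq_along(dims) + 1L] <- dims
  dim_field[dim_field == 0L] <- 1L
  pixdim_field <- c(1, pixdim, rep(1, 7L - length(dims)))

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")

  wb(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(36L), con)                        # data_type..dim_info
  wb(as.integer(dim_field), 2L)                  # dim[8]
  wb(numeric(3L), 4L)                            # intent_p1..p3
  wb(0L, 2L)                                     # intent_code
  wb(as.integer(datatype), 2L)                   # datatype
  wb(as.integer(dt$size * 8L), 2L)               # bitpix
  wb(0L, 2L)                                     # slice_start
  wb(as.numeric(pixdim_field), 4L)               # pixdim[8]
  wb(352, 4L)                                    # vox_offset
  wb(1, 4L)                                      # scl_slope
  wb(0, 4L)                                      # scl_inter
  wb(0L, 2L)                                     # slice_end
  writeBin(as.raw(c(0L, 2L)), con)               # slice_code, xyzt_units (mm)
  wb(numeric(4L), 4L)                            # cal_max..toffset
  wb(integer(2L), 4L)                            # glmax, glmin
  writeBin(raw(104L), con)                       # descrip, aux_file
  wb(integer(2L), 2L)                            # qform_code, sform_code
  wb(numeric(6L), 4L)                            # quaternion fields
  srow <- rbind(c(pixdim[1], 0, 0, 0),
                c(0, if (length(pixdim) > 1) pixdim[2] else 1, 0, 0),
                c(0, 0, if (length(pixdim) > 2) pixdim[3] else 1, 0))
  wb(as.numeric(t(srow)), 4L)                    # srow_x/y/z
  writeBin(raw(16L), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4L), con)                         # extension flag

  values <- as.vector(data)
  if (dt$mode == "integer") {
    values <- as.integer(round(values))
    writeBin(values, con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(values), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
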