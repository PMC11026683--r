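## Minimal NIfTI-1 reader/writer.
##
## No NIfTI package ships with this toolchain, and the format needs of the
## pipeline are narrow: little-endian single-file .nii(.gz), scalar dtypes,
## identity-style sform. This is NOT a general NIfTI implementation (no
## qform quaternions, extensions, or .hdr/.img pairs).

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)    # float64
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D or 4D array as a NIfTI-1 volume
#'
#' Writes a single-file little-endian NIfTI-1 image (float32 by default),
#' gzip-compressed when `path` ends in `.gz`. The sform is set to a diagonal
#' affine built from `pixdim` so standard readers accept the file.
#'
#' @param x numeric array with 3 or 4 dimensions.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param pixdim voxel sizes; for 4D data the 4th entry is the repetition
#'   time in seconds.
#' @param datatype NIfTI datatype code: 2 (uint8), 4 (int16), 8 (int32),
#'   16 (float32, default) or 64 (float64).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, pixdim = NULL, datatype = 16L) {
  nd <- length(dim(x))
  if (is.null(dim(x)) || nd < 3L || nd > 4L)
    stop("`x` must be a 3D or 4D array", call. = FALSE)
  spec <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype: ", datatype, call. = FALSE)
  if (is.null(pixdim)) pixdim <- rep(1, nd)
  if (length(pixdim) < nd) stop("`pixdim` shorter than image rank", call. = FALSE)

  dims <- rep(1L, 8L); dims[1L] <- nd; dims[1L + seq_len(nd)] <- dim(x)
  pd <- rep(0, 8L); pd[1L] <- 1; pd[1L + seq_len(nd)] <- pixdim[seq_len(nd)]

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wint <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wflt <- function(v) writeBin(as.double(v), con, size = 4L, endian = "little")
  wchr <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(len - length(raw))), con)
  }

  wint(348L, 4L)                     # sizeof_hdr
  wchr("", 10L); wchr("", 18L)       # data_type, db_name (unused)
  wint(0L, 4L); wint(0L, 2L)         # extents, session_error
  wchr("r", 1L); wchr("", 1L)        # regular, dim_info
  wint(dims, 2L)                     # dim[8]
  wflt(c(0, 0, 0))                   # intent_p1..3
  wint(0L, 2L)                       # intent_code
  wint(as.integer(datatype), 2L)     # datatype
  wint(spec$size * 8L, 2L)           # bitpix
  wint(0L, 2L)                       # slice_start
  wflt(pd)                           # pixdim[8]
  wflt(352)                          # vox_offset
  wflt(1); wflt(0)                   # scl_slope, scl_inter
  wint(0L, 2L); wchr("", 1L); wchr("", 1L)   # slice_end, slice_code, xyzt_units
  wflt(0); wflt(0)                   # cal_max, cal_min
  wflt(0); wflt(0)                   # slice_duration, toffset
  wint(0L, 4L); wint(0L, 4L)         # glmax, glmin
  wchr("capdyn synthetic volume", 80L)       # descrip
  wchr("", 24L)                      # aux_file
  wint(0L, 2L); wint(1L, 2L)         # qform_code = 0, sform_code = 1
  wflt(rep(0, 6))                    # quatern_b,c,d, qoffset_x,y,z
  wflt(c(pd[2L], 0, 0, 0))           # srow_x
  wflt(c(0, pd[3L], 0, 0))           # srow_y
  wflt(c(0, 0, pd[4L], 0))           # srow_z
  wchr("", 16L)                      # intent_name
  wchr("n+1", 4L)                    # magic
  writeBin(raw(4L), con)             # extension flag

  writeBin(if (spec$what == "double") as.double(x) else as.integer(x),
           con, size = spec$size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads single-file little-endian NIfTI-1 images written by [write_nifti()]
#' or other tools, supporting uint8/int16/int32/float32/float64 data with
#' scalar slope/intercept scaling.
#'
#' @param path file to read (`.nii` or `.nii.gz`).
#' @return list with `data` (array), `dim`, `pixdim`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  rint <- function(off, size, n = 1L)
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rflt <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L,
            endian = "little")
  if (rint(0L, 4L) != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr)", call. = FALSE)
  dims <- rint(40L, 2L, 8L)
  nd <- dims[1L]
  datatype <- rint(70L, 2L)
  pixdim <- rflt(76L, 8L)
  vox_offset <- rflt(108L)
  scl_slope <- rflt(112L)
  scl_inter <- rflt(116L)
  spec <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype: ", datatype, call. = FALSE)
  nvox <- prod(dims[1L + seq_len(nd)])
  skip <- vox_offset - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  dat <- readBin(con, spec$what, n = nvox, size = spec$size,
                 signed = spec$signed, endian = "little")
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    dat <- dat * scl_slope + scl_inter
  list(data = array(dat, dim = dims[1L + seq_len(nd)]),
       dim = dims[1L + seq_len(nd)],
       pixdim = pixdim[1L + seq_len(nd)])
}
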