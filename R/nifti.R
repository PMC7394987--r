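## Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
## No NIfTI package ships with this R stack, so the 348-byte header is
## handled directly: little-endian, sform affine, scl_slope/inter honored
## on read, no extensions. This intentionally covers only what the
## pipeline needs (3D/4D uint8 / int16 / int32 / float32 / float64).

.niftiDatatypes <- c(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                     float64 = 64L)
.niftiBitpix <- c(uint8 = 8L, int16 = 16L, int32 = 32L, float32 = 32L,
                  float64 = 64L)

.openMaybeGz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D/4D array as NIfTI-1
#'
#' Writes a single-file NIfTI-1 volume (gzipped when the path ends in
#' `.gz`) with the affine stored in the sform. `float64` (the default for
#' numeric data) round-trips R doubles bit-exactly.
#'
#' @param data 3D or 4D numeric/logical array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-world matrix (default: scaled identity from
#'   `pixdim`).
#' @param pixdim voxel size (mm), length 3, used when `affine` is missing.
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`; logicals default to `uint8`, numerics to `float64`.
#' @return `path`, invisibly.
#' @export
writeNifti <- function(data, path, affine = NULL, pixdim = c(1, 1, 1),
                       datatype = NULL) {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop("data must be a 3D or 4D array")
  if (is.null(datatype))
    datatype <- if (is.logical(data)) "uint8" else "float64"
  datatype <- match.arg(datatype, names(.niftiDatatypes))
  if (is.null(affine)) {
    affine <- diag(c(pixdim, 1))
  }
  stopifnot(identical(dim(affine), c(4L, 4L)))
  d <- dim(data)
  dimField <- rep(1L, 8L)
  dimField[1L] <- nd
  dimField[1L + seq_len(nd)] <- d
  pd <- rep(0, 8L)
  pd[2:4] <- sqrt(colSums(affine[1:3, 1:3]^2))
  con <- .openMaybeGz(path, "wb")
  on.exit(close(con))
  w <- function(x, size, what = "integer")
    writeBin(x, con, size = size, endian = "little")
  w(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(36L), con)                       # data_type..dim_info
  w(as.integer(dimField), 2L)                   # dim[8]
  writeBin(numeric(3L), con, size = 4L, endian = "little")  # intent_p1-3
  w(0L, 2L)                                     # intent_code
  w(.niftiDatatypes[[datatype]], 2L)            # datatype
  w(.niftiBitpix[[datatype]], 2L)               # bitpix
  w(0L, 2L)                                     # slice_start
  writeBin(pd, con, size = 4L, endian = "little")           # pixdim[8]
  writeBin(352, con, size = 4L, endian = "little")          # vox_offset
  writeBin(c(1, 0), con, size = 4L, endian = "little")      # scl_slope/inter
  w(0L, 2L)                                     # slice_end
  writeBin(as.raw(c(0L, 10L)), con)             # slice_code, xyzt_units=mm+s
  writeBin(numeric(4L), con, size = 4L, endian = "little")  # cal/slice/toff
  w(c(0L, 0L), 4L)                              # glmax, glmin
  desc <- charToRaw("bbbleak")
  writeBin(c(desc, raw(80L - length(desc))), con)           # descrip
  writeBin(raw(24L), con)                       # aux_file
  w(c(0L, 1L), 2L)                              # qform_code=0, sform_code=1
  writeBin(numeric(6L), con, size = 4L, endian = "little")  # quatern/qoffset
  writeBin(as.numeric(t(affine[1:3, ])), con, size = 4L,
           endian = "little")                   # srow_x/y/z
  writeBin(raw(16L), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)            # magic
  writeBin(raw(4L), con)                        # extension flag
  vals <- as.vector(data)
  if (datatype %in% c("float32", "float64")) {
    writeBin(as.numeric(vals), con,
             size = if (datatype == "float32") 4L else 8L,
             endian = "little")
  } else {
    writeBin(as.integer(vals), con,
             size = .niftiBitpix[[datatype]] / 8L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file little-endian NIfTI-1 volume written by
#' [writeNifti()] or any other writer of the same subset (e.g. nibabel).
#' Applies `scl_slope`/`scl_inter` when set.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return numeric array with attributes `affine` (4x4) and `pixdim`.
#' @export
readNifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- .openMaybeGz(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop(path, " is not a NIfTI-1 file (truncated)")
  ri <- function(off, n, size)
    readBin(hdr[(off + 1L):(off + n * size)], "integer", n = n,
            size = size, endian = "little")
  rf <- function(off, n, size = 4L)
    readBin(hdr[(off + 1L):(off + n * size)], "double", n = n,
            size = size, endian = "little")
  if (ri(0L, 1L, 4L) != 348L)
    stop(path, ": unsupported NIfTI header (not little-endian 348-byte)")
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop(path, " is not a NIfTI-1 file (bad magic)")
  dimField <- ri(40L, 8L, 2L)
  nd <- dimField[1L]
  if (!nd %in% c(2L, 3L, 4L)) stop("unsupported dimensionality: ", nd)
  d <- dimField[1L + seq_len(nd)]
  datatype <- ri(70L, 1L, 2L)
  pixdim <- rf(76L, 8L)[2:4]
  voxOffset <- rf(108L, 1L)
  slope <- rf(112L, 1L)
  inter <- rf(116L, 1L)
  sformCode <- ri(254L, 1L, 2L)
  srow <- rf(280L, 12L)
  affine <- if (sformCode > 0L) {
    rbind(matrix(srow, nrow = 3L, byrow = TRUE), c(0, 0, 0, 1))
  } else diag(c(pixdim, 1))
  ## skip to the data
  readBin(con, "raw", n = max(0L, as.integer(voxOffset) - 348L))
  n <- prod(d)
  code <- names(.niftiDatatypes)[match(datatype, .niftiDatatypes)]
  if (is.na(code)) stop("unsupported NIfTI datatype code ", datatype)
  vals <- if (code %in% c("float32", "float64")) {
    readBin(con, "double", n = n, size = .niftiBitpix[[code]] / 8L,
            endian = "little")
  } else if (code == "uint8") {
    as.integer(readBin(con, "raw", n = n))
  } else {
    readBin(con, "integer", n = n, size = .niftiBitpix[[code]] / 8L,
            endian = "little")
  }
  if (length(vals) != n) stop(path, ": data shorter than header promises")
  if (is.finite(slope) && slope != 0 && !(slope == 1 && inter == 0))
    vals <- vals * slope + inter
  out <- array(vals, dim = d)
  attr(out, "affine") <- affine
  attr(out, "pixdim") <- pixdim
  out
}

#' Check two affines agree
#'
#' Volumes are combined index-wise, so their voxel-to-world affines must
#' match; a mismatch beyond `tol` is an error naming both affines.
#'
#' @param a,b 4x4 affine matrices.
#' @param tol maximum absolute elementwise difference (default 1e-4).
#' @return invisibly `TRUE` when they match.
#' @export
checkAffineMatch <- function(a, b, tol = 1e-4) {
  if (max(abs(a - b)) > tol) {
    fmt <- function(m) paste(apply(round(m, 6), 1L, paste, collapse = " "),
                             collapse = "; ")
    stop("affine mismatch beyond tolerance ", tol, ":\n  first:  ",
         fmt(a), "\n  second: ", fmt(b))
  }
  invisible(TRUE)
}

.sidecarPath <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write / read a dynamic series as NIfTI + JSON sidecar
#'
#' The 4D signal goes into the NIfTI file; the time stamps, sequence role
#' and pre-contrast volume count go into a JSON sidecar next to it
#' (same basename, `.json`). Reading without the sidecar is an error with a
#' remediation hint.
#'
#' @param series a [DynamicSeries-class].
#' @param path `.nii` / `.nii.gz` path.
#' @param affine 4x4 affine.
#' @return `writeDynamicSeries`: `path` invisibly; `readDynamicSeries`: a
#'   [DynamicSeries-class] with attribute `affine`.
#' @export
writeDynamicSeries <- function(series, path, affine = diag(4)) {
  stopifnot(is(series, "DynamicSeries"))
  writeNifti(series@data, path, affine = affine)
  jsonlite::write_json(
    list(times_s = series@times, role = series@role,
         n_precontrast = series@nPrecontrast),
    .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDynamicSeries
#' @export
readDynamicSeries <- function(path) {
  sp <- .sidecarPath(path)
  if (!file.exists(sp))
    stop("4D series ", path, " has no JSON sidecar ", sp,
         "; write it with writeDynamicSeries() or provide times_s, role ",
         "and n_precontrast alongside the volume")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  img <- readNifti(path)
  aff <- attr(img, "affine")
  img <- array(as.vector(img), dim = dim(img))   # strip reader attributes
  out <- dynamicSeries(img, meta$times_s, meta$role, meta$n_precontrast)
  attr(out, "affine") <- aff
  out
}
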