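# Minimal NIfTI-1 I/O. The pre-installed R stack carries no NIfTI package, so
# the 348-byte header is parsed directly; gzipped files are handled through
# gzfile(). Only what a CT pipeline needs is supported: 3D scalar volumes,
# integer/float datatypes, scl slope/intercept, sform/qform geometry.

.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE))  # uint16

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return a `ct_volume` (values with scale slope/intercept applied; affine
#'   from sform if set, else qform, else pixdim).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L) stop("corrupt NIfTI file (short header): ", path)
  rint <- function(off, n, size, signed = TRUE, endian = "little")
    readBin(hdr_raw[(off + 1):(off + n * size)], "integer", n, size,
            signed = signed, endian = endian)
  sizeof_hdr <- rint(0, 1, 4)
  endian <- "little"
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- rint(0, 1, 4, endian = "big")
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  rflt <- function(off, n)
    readBin(hdr_raw[(off + 1):(off + n * 4)], "double", n, 4, endian = endian)
  rshort <- function(off, n) rint(off, n, 2, endian = endian)

  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  dims <- rshort(40, 8)
  ndim <- dims[1]
  if (ndim < 3 || prod(pmax(dims[5:8][seq_len(max(0, ndim - 3))], 1L)) != 1)
    stop("only 3D scalar volumes are supported (got dim = ",
         paste(dims[2:(1 + ndim)], collapse = "x"), ")")
  d3 <- dims[2:4]
  datatype <- rshort(70, 1)
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- rflt(76, 8)
  vox_offset <- rflt(108, 1)
  scl_slope <- rflt(112, 1)
  scl_inter <- rflt(116, 1)
  qform_code <- rshort(252, 1)
  sform_code <- rshort(254, 1)

  affine <- NULL
  if (sform_code > 0) {
    affine <- rbind(rflt(280, 4), rflt(296, 4), rflt(312, 4), c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    b <- rflt(256, 1); c_ <- rflt(260, 1); d_ <- rflt(264, 1)
    a2 <- 1 - b^2 - c_^2 - d_^2
    a <- sqrt(max(a2, 0))
    Rm <- matrix(c(
      a^2 + b^2 - c_^2 - d_^2, 2 * (b * c_ + a * d_),   2 * (b * d_ - a * c_),
      2 * (b * c_ - a * d_),   a^2 + c_^2 - b^2 - d_^2, 2 * (c_ * d_ + a * b),
      2 * (b * d_ + a * c_),   2 * (c_ * d_ - a * b),   a^2 + d_^2 - b^2 - c_^2),
      3, 3)
    qfac <- if (pixdim[1] < 0) -1 else 1
    Rm <- Rm %*% diag(c(pixdim[2:3], qfac * pixdim[4]))
    affine <- rbind(cbind(Rm, rflt(268, 3)), c(0, 0, 0, 1))
  } else {
    affine <- diag(c(pixdim[2:4], 1))
  }

  n <- prod(d3)
  if (magic == "ni1") stop("detached NIfTI .hdr/.img pairs are not supported")
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (length(vals) < n) stop("corrupt NIfTI file (truncated data): ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0)
    vals <- vals * scl_slope + scl_inter
  dim(vals) <- d3
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  ct_volume(vals, spacing, affine, source_id = path)
}

#' Write a volume as NIfTI-1 (float32, sform geometry)
#'
#' @param vol a `ct_volume`, or a `cluster_labeling` / `binary_volume` (their
#'   grids are written as the data).
#' @param path output file; gzip-compressed when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  values <- if (inherits(vol, "ct_volume")) vol$values
            else if (!is.null(vol$labels)) vol$labels
            else if (!is.null(vol$mask)) vol$mask + 0
            else stop("cannot extract a grid from this object")
  affine <- vol$affine
  spacing <- vol$spacing
  d3 <- dim(values)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, 4L, endian = "little")
  wi(348, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                       # unused + dim_info
  wi(c(3, d3, 1, 1, 1, 1), 2)                  # dim[8]
  writeBin(raw(14), con)                       # intent_p1..3, intent_code
  wi(16, 2); wi(32, 2)                         # datatype float32, bitpix
  wi(0, 2)                                     # slice_start
  wf(c(1, spacing, 0, 0, 0, 0))                # pixdim[8] (qfac = 1)
  wf(352); wf(1); wf(0)                        # vox_offset, scl_slope, scl_inter
  writeBin(raw(3), con); writeBin(raw(1), con) # slice_end/code, xyzt_units
  wf(c(max(values), min(values), 0, 0))        # cal_max/min, slice_dur, toffset
  wi(c(0, 0), 4)                               # glmax, glmin
  writeBin(raw(80 + 24), con)                  # descrip, aux_file
  wi(0, 2); wi(2, 2)                           # qform_code 0, sform_code 2
  wf(rep(0, 6))                                # quaternions + offsets
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])
  writeBin(raw(16), con)                       # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)
  writeBin(raw(4), con)                        # extension flag
  writeBin(as.double(values), con, 4L, endian = "little")
  invisible(path)
}
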