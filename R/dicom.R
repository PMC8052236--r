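# Minimal single-series DICOM reader (explicit and implicit VR little
# endian). Enough of Part 10 is parsed to recover geometry and rescaled HU
# values from one CT series; anything exotic (compressed transfer syntaxes,
# multiframe) is rejected with a clear error.

.dcm_tag <- function(group, elem) sprintf("%04x,%04x", group, elem)

.dcm_parse_file <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  buf <- readBin(con, "raw", sz)
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 132L  # 0-based offset of next byte to read
  n <- length(buf)
  u16 <- function(at) readBin(buf[(at + 1):(at + 2)], "integer", 1, 2,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(buf[(at + 1):(at + 4)], "integer", 1, 4,
                              endian = "little")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  elems <- list()
  explicit <- TRUE   # file meta group is always explicit LE
  ts <- NULL

  read_elem <- function(pos, explicit) {
    group <- u16(pos); elem <- u16(pos + 2)
    if (explicit && group != 0xFFFE) {
      vr <- rawToChar(buf[(pos + 5):(pos + 6)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8); hdr <- 12L
      } else {
        len <- u16(pos + 6); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(pos + 4); hdr <- 8L
    }
    list(group = group, elem = elem, vr = vr, len = len, hdr = hdr)
  }
  # skip an undefined-length sequence by walking items
  skip_undefined <- function(pos) {
    repeat {
      g <- u16(pos); e <- u16(pos + 2); len <- u32(pos + 4)
      pos <- pos + 8L
      if (g == 0xFFFE && e == 0xE0DD) return(pos)
      if (len == -1L) pos <- skip_undefined(pos)   # nested undefined item
      else pos <- pos + len
    }
  }

  raw2str <- function(r) trimws(rawToChar(r[r != as.raw(0)]))
  meta_done <- FALSE
  while (pos + 8 <= n) {
    if (!meta_done && u16(pos) > 0x0002) {
      # leaving the (always explicit-LE) file meta group
      if (is.null(ts))
        stop("DICOM file without transfer syntax UID: ", path)
      if (!ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        stop("unsupported DICOM transfer syntax ", ts, " in ", path)
      explicit <- ts != "1.2.840.10008.1.2"
      meta_done <- TRUE
    }
    el <- read_elem(pos, explicit)
    body <- pos + el$hdr
    if (el$len == -1L) {                 # undefined length (sequence)
      pos <- skip_undefined(body)
      next
    }
    if (body + el$len > n) stop("corrupt DICOM file (truncated): ", path)
    tag <- .dcm_tag(el$group, el$elem)
    keep <- c("0002,0010", "0020,000e", "0020,0032", "0020,0037",
              "0028,0010", "0028,0011", "0028,0030", "0028,0100",
              "0028,0103", "0028,1052", "0028,1053", "7fe0,0010")
    if (tag %in% keep && el$len > 0)
      elems[[tag]] <- list(vr = el$vr, raw = buf[(body + 1):(body + el$len)])
    pos <- body + el$len
    if (el$group == 0x0002 && el$elem == 0x0010)
      ts <- raw2str(elems[["0002,0010"]]$raw)
  }

  txt <- function(tag) {
    e <- elems[[tag]]
    if (is.null(e)) return(NULL)
    raw2str(e$raw)
  }
  nums <- function(tag) {
    v <- txt(tag)
    if (is.null(v)) return(NULL)
    as.numeric(strsplit(v, "\\\\")[[1]])
  }
  us <- function(tag) {
    e <- elems[[tag]]
    if (is.null(e)) return(NULL)
    readBin(e$raw, "integer", 1, 2, signed = FALSE, endian = "little")
  }
  rows <- us("0028,0010"); cols <- us("0028,0011")
  bits <- us("0028,0100"); pixrep <- us("0028,0103")
  if (is.null(rows) || is.null(cols) || is.null(elems[["7fe0,0010"]]))
    stop("DICOM file missing image data: ", path)
  if (is.null(bits)) bits <- 16L
  if (bits != 16L) stop("only 16-bit DICOM pixel data is supported: ", path)
  px <- readBin(elems[["7fe0,0010"]]$raw, "integer", rows * cols, 2,
                signed = !is.null(pixrep) && pixrep == 1L, endian = "little")
  slope <- nums("0028,1053"); if (is.null(slope)) slope <- 1
  inter <- nums("0028,1052"); if (is.null(inter)) inter <- 0
  list(series_uid = txt("0020,000e"),
       ipp = nums("0020,0032"), iop = nums("0020,0037"),
       pixel_spacing = nums("0028,0030"),
       rows = rows, cols = cols,
       hu = matrix(px * slope + inter, nrow = cols))  # [x = column, y = row]
}

#' Read a directory containing one DICOM series
#'
#' Slices are sorted along the series normal; rescale slope/intercept are
#' applied so values are Hounsfield units.
#'
#' @param path directory of DICOM slice files from a single series.
#' @return a `ct_volume`.
#' @export
read_dicom_series <- function(path) {
  if (!dir.exists(path)) stop("not a directory: ", path)
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in DICOM directory: ", path)
  slices <- lapply(sort(files), .dcm_parse_file)
  uids <- unique(vapply(slices, function(s) s$series_uid %||% "<none>", ""))
  if (length(uids) > 1)
    stop("directory contains multiple DICOM series: ",
         paste(uids, collapse = ", "))
  s1 <- slices[[1]]
  if (is.null(s1$iop) || is.null(s1$ipp) || is.null(s1$pixel_spacing))
    stop("DICOM series lacks geometry tags (ImageOrientation/Position)")
  rdir <- s1$iop[1:3]; cdir <- s1$iop[4:6]
  normal <- c(rdir[2] * cdir[3] - rdir[3] * cdir[2],
              rdir[3] * cdir[1] - rdir[1] * cdir[3],
              rdir[1] * cdir[2] - rdir[2] * cdir[1])
  proj <- vapply(slices, function(s) sum(s$ipp * normal), 0)
  ord <- order(proj)
  slices <- slices[ord]; proj <- proj[ord]
  nz <- length(slices)
  if (nz > 1) {
    dz <- diff(proj)
    if (any(dz <= 1e-6))
      stop("non-monotonic slice positions in DICOM series (duplicate or ",
           "interleaved slices)")
    if (max(dz) - min(dz) > 0.01 * mean(dz))
      stop("non-uniform slice spacing in DICOM series")
    # gantry tilt: in-plane drift of slice origins is not corrected
    ipp1 <- slices[[1]]$ipp; ippN <- slices[[nz]]$ipp
    step <- (ippN - ipp1) / (nz - 1)
    inplane <- step - sum(step * normal) * normal
    if (sqrt(sum(inplane^2)) > 0.05 * mean(dz))
      stop("tilted-gantry DICOM series are not supported")
    slice_sp <- mean(dz)
  } else slice_sp <- 1
  nx <- s1$cols; ny <- s1$rows
  vals <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    if (slices[[k]]$cols != nx || slices[[k]]$rows != ny)
      stop("inconsistent slice dimensions in DICOM series")
    vals[, , k] <- slices[[k]]$hu
  }
  # PixelSpacing = (row spacing, column spacing)
  sp <- c(s1$pixel_spacing[2], s1$pixel_spacing[1], slice_sp)
  A <- diag(4)
  A[1:3, 1] <- rdir * sp[1]
  A[1:3, 2] <- cdir * sp[2]
  A[1:3, 3] <- normal * sp[3]
  A[1:3, 4] <- slices[[1]]$ipp
  ct_volume(vals, sp, A, source_id = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
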