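# Shared fixtures: voxel-set rasterizers, an independent brute-force moment
# oracle, tiny labeled datasets, and byte-level NIfTI/DICOM fixture writers.
# Everything is generated in code at test time; nothing binary ships.

# ---- voxel-set rasterizers (0-based integer coordinates) ----

vox_cube <- function(side) {
  as.matrix(expand.grid(0:(side - 1), 0:(side - 1), 0:(side - 1)))
}

vox_sphere <- function(radius) {
  r <- ceiling(radius)
  g <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

# solid disc: diameter/thickness in voxels, axis along z
vox_disc <- function(diameter, thickness) {
  r <- diameter / 2
  rr <- ceiling(r)
  g <- as.matrix(expand.grid(-rr:rr, -rr:rr, 0:(thickness - 1)))
  g[g[, 1]^2 + g[, 2]^2 <= r^2, , drop = FALSE]
}

# disc rasterized with its axis rotated by `theta` about the y axis
vox_disc_rotated <- function(diameter, thickness, theta) {
  r <- diameter / 2
  b <- ceiling(r + thickness)
  g <- as.matrix(expand.grid(-b:b, -b:b, -b:b))
  ax <- c(sin(theta), 0, cos(theta))
  a <- g %*% ax
  rad2 <- rowSums(g^2) - a^2
  g[abs(a) <= thickness / 2 & rad2 <= r^2, , drop = FALSE]
}

# ---- independent oracle: brute-force central moments -> axis lengths ----
# Deliberately computes centered sums voxel by voxel, unlike the package's
# sufficient-statistics route.

oracle_axis_lengths <- function(vox) {
  vox <- matrix(as.numeric(vox), ncol = 3)
  n <- nrow(vox)
  ctr <- colMeans(vox)
  M <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    d <- vox[i, ] - ctr
    M <- M + outer(d, d)
  }
  M <- M / n + diag(1 / 12, 3)
  sort(2 * sqrt(5 * eigen(M, symmetric = TRUE)$values), decreasing = TRUE)
}

# random 6-connected-ish small cluster grown by a voxel random walk
random_cluster <- function(n_voxels, seed) {
  set.seed(seed)
  pts <- matrix(c(0, 0, 0), 1)
  while (nrow(pts) < n_voxels) {
    base <- pts[sample.int(nrow(pts), 1), ]
    step <- diag(3)[sample.int(3, 1), ] * sample(c(-1, 1), 1)
    pts <- unique(rbind(pts, base + step))
  }
  pts
}

# ---- labeling fixtures ----

labeling_from_mask <- function(mask, spacing = c(1, 1, 1), affine = NULL) {
  bv <- structure(list(mask = mask, spacing = spacing,
                       affine = if (is.null(affine)) diag(c(spacing, 1))
                                else affine),
                  class = "binary_volume")
  label_clusters(bv)
}

mask_from_voxels <- function(vox, pad = 2L) {
  vox <- sweep(vox, 2, apply(vox, 2, min)) + pad  # 0-based, shifted positive
  dims <- apply(vox, 2, max) + pad + 1L
  m <- array(FALSE, dims)
  m[vox + 1L] <- TRUE
  m
}

# ---- small labeled datasets for the classifier ----

blobs_dataset <- function(n_per = 50, sep = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per * 2), ncol = 2),
             matrix(stats::rnorm(n_per * 2) + sep, ncol = 2))
  colnames(X) <- c("volume", "circularity")
  structure(list(features = X,
                 labels = rep(c("ECOG", "NON_ELECTRODE"), each = n_per),
                 groups = rep(c("a", "b"), each = n_per), name = "blobs",
                 feature_names = colnames(X)),
            class = "labeled_dataset")
}

xor_dataset <- function(n_per = 25, seed = 2) {
  set.seed(seed)
  corners <- expand.grid(s1 = c(0, 1), s2 = c(0, 1))
  X <- do.call(rbind, lapply(1:4, function(i)
    cbind(stats::rnorm(n_per, corners$s1[i] * 6),
          stats::rnorm(n_per, corners$s2[i] * 6))))
  colnames(X) <- c("volume", "circularity")
  lab <- unlist(lapply(1:4, function(i)
    rep(if (xor(corners$s1[i], corners$s2[i])) "ECOG" else "NON_ELECTRODE",
        n_per)))
  structure(list(features = X, labels = lab, groups = rep("p", 4 * n_per),
                 name = "xor", feature_names = colnames(X)),
            class = "labeled_dataset")
}

shuffle_dataset <- function(ds, seed) {
  set.seed(seed)
  i <- sample.int(length(ds$labels))
  structure(list(features = ds$features[i, , drop = FALSE],
                 labels = ds$labels[i], groups = ds$groups[i],
                 name = ds$name, feature_names = ds$feature_names),
            class = "labeled_dataset")
}

# ---- minimal DICOM fixture writer (explicit VR little endian) ----
# Crafted tag by tag so the package's reader is tested against independent
# bytes, not its own writer.

dcm_elem <- function(group, elem, vr, value_raw) {
  hdr <- c(writeBin(as.integer(group), raw(), 2, endian = "little"),
           writeBin(as.integer(elem), raw(), 2, endian = "little"),
           charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, raw(2),
      writeBin(length(value_raw), raw(), 4, endian = "little"), value_raw)
  } else {
    c(hdr, writeBin(as.integer(length(value_raw)), raw(), 2,
                    endian = "little"), value_raw)
  }
}

dcm_str <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
  r
}

dcm_ui <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, raw(1))
  r
}

dcm_us <- function(x) writeBin(as.integer(x), raw(), 2, endian = "little")

write_dicom_slice <- function(path, pixels, ipp, series_uid = "1.2.3.4",
                              pixel_spacing = c(0.8, 0.7),
                              iop = c(1, 0, 0, 0, 1, 0),
                              slope = 1, intercept = -1024) {
  # pixels: matrix [col, row] of stored values
  ncol_img <- nrow(pixels)  # columns (x)
  nrow_img <- ncol(pixels)  # rows (y)
  px <- integer(0)
  for (r in seq_len(nrow_img)) px <- c(px, pixels[, r])
  px_raw <- writeBin(as.integer(px), raw(), 2, endian = "little")
  meta <- dcm_elem(0x0002, 0x0010, "UI", dcm_ui("1.2.840.10008.1.2.1"))
  body <- c(
    dcm_elem(0x0020, 0x000E, "UI", dcm_ui(series_uid)),
    dcm_elem(0x0020, 0x0032, "DS", dcm_str(paste(ipp, collapse = "\\"))),
    dcm_elem(0x0020, 0x0037, "DS", dcm_str(paste(iop, collapse = "\\"))),
    dcm_elem(0x0028, 0x0010, "US", dcm_us(nrow_img)),
    dcm_elem(0x0028, 0x0011, "US", dcm_us(ncol_img)),
    dcm_elem(0x0028, 0x0030, "DS",
             dcm_str(paste(pixel_spacing, collapse = "\\"))),
    dcm_elem(0x0028, 0x0100, "US", dcm_us(16)),
    dcm_elem(0x0028, 0x0103, "US", dcm_us(0)),
    dcm_elem(0x0028, 0x1052, "DS", dcm_str(as.character(intercept))),
    dcm_elem(0x0028, 0x1053, "DS", dcm_str(as.character(slope))),
    dcm_elem(0x7FE0, 0x0010, "OW", px_raw))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# ---- shared phantom corpora (built lazily, once per test run) ----

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

t3_corpus <- function() {
  cached("t3", {
    tabs <- lapply(1:12, function(i)
      phantom_pipeline(
        phantom_spec(strips = c(8, 12), grids = list(c(8, 8)),
                     n_wires = 25, n_stitches = 350, n_screws = 45,
                     seed = 100 + i),
        patient_id = sprintf("ph%02d", i))$features)
    assemble_dataset(tabs, "t3_corpus")
  })
}

t2_phantoms <- function() {
  cached("t2", lapply(1:6, function(i)
    phantom_pipeline(phantom_spec(seed = i),
                     patient_id = sprintf("t2_%d", i))))
}
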