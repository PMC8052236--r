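#' CT volume container
#'
#' A `ct_volume` holds a 3D grid of radiodensities in Hounsfield units (HU)
#' together with its per-axis voxel spacing (mm) and a 4x4 affine mapping
#' 0-based voxel indices to world coordinates in mm. The affine's linear-part
#' column norms must equal the spacing.
#'
#' @param values 3D numeric array of HU values.
#' @param spacing numeric length-3, voxel size in mm per axis (> 0).
#' @param affine 4x4 voxel-index (0-based) to world-mm matrix; defaults to
#'   `diag(c(spacing, 1))` (axis-aligned, origin at the first voxel center).
#' @param source_id free-text provenance tag.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing, affine = NULL, source_id = "memory") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  spacing <- as.numeric(spacing)
  if (is.null(affine))
    affine <- diag(c(spacing, 1))
  vol <- structure(
    list(values = values, spacing = spacing, affine = affine,
         source_id = as.character(source_id)[1]),
    class = "ct_volume")
  validate_ct_volume(vol)
  vol
}

#' Validate a ct_volume's invariants
#'
#' Checks positive finite spacing, an invertible affine whose linear-part
#' column norms match the spacing (1e-6 relative), and a non-empty grid.
#'
#' @param vol a `ct_volume`.
#' @return `vol`, invisibly; errors if an invariant is violated.
#' @export
validate_ct_volume <- function(vol) {
  if (!inherits(vol, "ct_volume")) stop("not a ct_volume")
  sp <- vol$spacing
  if (length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0))
    stop("spacing must be 3 strictly positive finite values")
  if (any(dim(vol$values) < 1L)) stop("grid must have >= 1 voxel per axis")
  A <- vol$affine
  if (!is.matrix(A) || any(dim(A) != 4L)) stop("affine must be 4x4")
  if (abs(det(A)) < 1e-12) stop("affine must be invertible")
  cn <- sqrt(colSums(A[1:3, 1:3]^2))
  if (any(abs(cn - sp) > 1e-6 * pmax(sp, 1)))
    stop("affine column norms must equal spacing (1e-6 relative)")
  invisible(vol)
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("ct_volume: %s\n  grid %s, spacing %s mm\n  HU range [%.1f, %.1f]\n",
              x$source_id, paste(dim(x$values), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Map voxel indices to world coordinates
#'
#' @param vol a `ct_volume` (or anything with an `affine`).
#' @param idx0 n x 3 matrix of 0-based voxel indices (fractional allowed).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(vol, idx0) {
  idx0 <- matrix(as.numeric(idx0), ncol = 3)
  h <- cbind(idx0, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE]
}

#' Resample a CT volume to isotropic cubic voxels
#'
#' Interpolating cubic B-spline resampling (prefiltered third-order spline,
#' no smoothing) onto a cell-centered grid anchored at the input's first
#' voxel center. Output size per axis is `floor(n * spacing / target)` with a
#' minimum of 1; coordinates outside the input extent take the nearest-edge
#' value. With the paper-default target of 0.5 mm this makes the downstream
#' shape descriptors rotationally invariant.
#'
#' @param vol a `ct_volume`.
#' @param target_spacing target cubic voxel side in mm (default 0.5).
#' @param clamp_range optional length-2 numeric; clamp interpolated values to
#'   this HU range (spline overshoot near metal edges is tolerated by
#'   default, since the metal threshold sits far above soft tissue).
#' @return a `ct_volume` with spacing `rep(target_spacing, 3)`.
#' @export
resample_isotropic <- function(vol, target_spacing = 0.5, clamp_range = NULL) {
  validate_ct_volume(vol)
  if (!is.numeric(target_spacing) || length(target_spacing) != 1 ||
      !is.finite(target_spacing) || target_spacing <= 0)
    stop("target_spacing must be a single positive number")
  d <- dim(vol$values)
  scl <- target_spacing / vol$spacing
  out_dims <- pmax(1L, as.integer(floor(d * vol$spacing / target_spacing)))
  vals <- .cpp_resample_bspline(as.double(vol$values), as.integer(d),
                                as.double(scl), out_dims)
  if (!is.null(clamp_range)) {
    vals[vals < clamp_range[1]] <- clamp_range[1]
    vals[vals > clamp_range[2]] <- clamp_range[2]
  }
  A <- vol$affine
  A[1:3, 1:3] <- A[1:3, 1:3] %*% diag(scl)
  ct_volume(vals, rep(target_spacing, 3), A,
            source_id = paste0(vol$source_id, ":iso", signif(target_spacing, 3)))
}

# Reorient a volume so the affine's linear part is (near-)diagonal with
# positive diagonal, by axis permutation and flips. Voxel-space operations
# then see a canonical right-handed frame whatever the acquisition order was.
canonical_orientation <- function(vol) {
  L <- vol$affine[1:3, 1:3]
  D <- sweep(L, 2, sqrt(colSums(L^2)), "/")
  perm <- integer(3)   # perm[w]: input axis that maps to world axis w
  usedw <- rep(FALSE, 3); useda <- rep(FALSE, 3)
  for (p in order(-abs(D))) {   # greedy by |direction cosine|
    w <- (p - 1) %% 3 + 1
    a <- (p - 1) %/% 3 + 1
    if (!usedw[w] && !useda[a]) {
      perm[w] <- a; usedw[w] <- TRUE; useda[a] <- TRUE
    }
  }
  flip <- D[cbind(1:3, perm)] < 0
  if (all(perm == 1:3) && !any(flip)) return(vol)
  vals <- aperm(vol$values, perm)
  A <- vol$affine
  Anew <- diag(4)
  Anew[1:3, 1:3] <- A[1:3, perm]
  Anew[1:3, 4] <- A[1:3, 4]
  d <- dim(vals)
  for (w in 1:3) {
    if (flip[w]) {
      idx <- rev(seq_len(d[w]))
      vals <- switch(w, vals[idx, , , drop = FALSE],
                     vals[, idx, , drop = FALSE], vals[, , idx, drop = FALSE])
      Anew[1:3, 4] <- Anew[1:3, 4] + Anew[1:3, w] * (d[w] - 1)
      Anew[1:3, w] <- -Anew[1:3, w]
    }
  }
  ct_volume(vals, vol$spacing[perm], Anew, source_id = vol$source_id)
}

#' Load a CT volume from NIfTI or a DICOM series directory
#'
#' Values are returned in Hounsfield units (NIfTI scale slope/intercept and
#' DICOM rescale slope/intercept applied). The volume is reoriented to a
#' canonical right-handed axis-aligned frame, recorded in the affine.
#'
#' @param path a NIfTI file (`.nii` / `.nii.gz`) or a directory containing a
#'   single DICOM series.
#' @param format_hint optional, one of `"nifti"`, `"dicom_dir"`; inferred
#'   from `path` when omitted.
#' @return a `ct_volume`.
#' @export
load_ct <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- format_hint
  if (is.null(fmt))
    fmt <- if (dir.exists(path)) "dicom_dir" else "nifti"
  fmt <- match.arg(fmt, c("nifti", "dicom_dir"))
  vol <- switch(fmt,
                nifti = read_nifti(path),
                dicom_dir = read_dicom_series(path))
  canonical_orientation(vol)
}
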