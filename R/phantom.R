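# Synthetic post-implant head CT phantom. The scene is a spherical "head"
# (soft tissue with a skull shell) carrying disc-electrode strips and grids
# placed on the brain surface at their nominal pitch, plus the distractors a
# real post-implant CT contains: connecting wires, stitches/clips and bone
# screws. Metal is painted at its pre-blur radiodensity, the volume is
# convolved with a Gaussian point-spread function, clipped at the scanner's
# HU ceiling and corrupted with additive noise -- which reproduces the
# partial-volume inflation of electrode volumes the method has to live with.

#' Phantom scene specification
#'
#' Defaults emulate the acquisition and hardware this pipeline targets:
#' 4 mm x 0.5 mm platinum discs at 10 mm pitch in strips of 8 and 12 plus a
#' 6x8 grid, in-plane pixel size drawn from 0.44-0.98 mm with 0.625 mm
#' slices, metal far denser than compact bone.
#'
#' @param grid_shape voxels per axis; default: derived from `head_radius`
#'   and `spacing` (head plus a 16 mm margin).
#' @param spacing mm per axis; default: in-plane size drawn uniformly from
#'   0.44-0.98 mm (from the seed), slice thickness 0.625 mm.
#' @param head_radius brain-surface radius in mm (default 45; desk-scale).
#' @param skull_hu,metal_hu,background_hu radiodensities (HU). `metal_hu` is
#'   the *pre-blur* metal value (default 25000: platinum saturates the HU
#'   scale; after the PSF the observed metal peaks at `clip_hu`).
#' @param clip_hu post-blur HU ceiling (default 3071, 12-bit scanner scale).
#' @param psf_sigma Gaussian point-spread sigma in mm (default 0.4).
#' @param noise_sigma additive noise sigma in HU (default 15).
#' @param strips electrode counts per strip, from {4, 6, 8, 12}.
#' @param grids list of (rows, cols) grids, e.g. `list(c(8, 8))`.
#' @param electrode_diameter,electrode_thickness,electrode_spacing disc
#'   geometry in mm (defaults 4, 0.5, 10).
#' @param n_wires,n_stitches,n_screws distractor counts.
#' @param depth_arrays list of numeric vectors
#'   `c(n_contacts, contact_length_mm, contact_diameter_mm, pitch_mm)`.
#' @param depth_fused paint a continuous shaft through the depth contacts so
#'   they fuse into one cluster.
#' @param overlap_electrode_pairs number of deliberately overlapped
#'   electrode pairs (each fuses into a single cluster).
#' @param seed integer; the phantom is deterministic given the spec + seed.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = NULL, spacing = NULL, head_radius = 45,
                         skull_hu = 1500, metal_hu = 25000, clip_hu = 3071,
                         background_hu = 40, psf_sigma = 0.4, noise_sigma = 15,
                         strips = c(8, 12), grids = list(c(6, 8)),
                         electrode_diameter = 4, electrode_thickness = 0.5,
                         electrode_spacing = 10,
                         n_wires = 10, n_stitches = 15, n_screws = 2,
                         depth_arrays = list(), depth_fused = FALSE,
                         overlap_electrode_pairs = 0, seed = 1L) {
  stopifnot(head_radius > 0, electrode_diameter > 0, electrode_thickness > 0,
            electrode_spacing > 0, psf_sigma >= 0, noise_sigma >= 0,
            n_wires >= 0, n_stitches >= 0, n_screws >= 0,
            overlap_electrode_pairs >= 0)
  if (electrode_spacing <= electrode_diameter)
    stop("electrode_spacing must exceed electrode_diameter")
  if (!is.null(spacing) && (length(spacing) != 3 || any(spacing <= 0)))
    stop("spacing must be 3 positive values")
  if (length(strips) && !all(strips >= 2))
    stop("strips need >= 2 electrodes")
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 head_radius = head_radius, skull_hu = skull_hu,
                 metal_hu = metal_hu, clip_hu = clip_hu,
                 background_hu = background_hu, psf_sigma = psf_sigma,
                 noise_sigma = noise_sigma, strips = strips, grids = grids,
                 electrode_diameter = electrode_diameter,
                 electrode_thickness = electrode_thickness,
                 electrode_spacing = electrode_spacing,
                 n_wires = n_wires, n_stitches = n_stitches,
                 n_screws = n_screws, depth_arrays = depth_arrays,
                 depth_fused = depth_fused,
                 overlap_electrode_pairs = overlap_electrode_pairs,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

.runit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

.tangent_basis <- function(n, angle = 0) {
  u <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- u - sum(u * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = cos(angle) * e1 + sin(angle) * e2,
       e2 = -sin(angle) * e1 + cos(angle) * e2)
}

#' Generate a synthetic post-implant head CT with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a `ct_volume` at the spec's anisotropic
#'   acquisition spacing) and `truth` (data.frame: `object_id`, `class`,
#'   `x_mm`, `y_mm`, `z_mm`, `geometry`), one row per generated metal
#'   object with its exact painted-voxel centroid.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("not a phantom_spec")
  set.seed(spec$seed)
  sp <- spec$spacing
  if (is.null(sp)) {
    sxy <- stats::runif(1, 0.44, 0.98)
    sp <- c(sxy, sxy, 0.625)
  }
  R <- spec$head_radius
  fov <- 2 * (R + 16)
  dims <- spec$grid_shape
  if (is.null(dims)) dims <- as.integer(ceiling(fov / sp))
  if (any(dims < 8)) stop("phantom grid too small")
  cen <- (dims - 1) * sp / 2
  if (min((dims - 1) * sp) < 2 * (R + 10))
    stop("head of radius ", R, " mm does not fit in the phantom grid")

  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ax <- (seq_len(nx) - 1) * sp[1] - cen[1]
  ay <- (seq_len(ny) - 1) * sp[2] - cen[2]
  az <- (seq_len(nz) - 1) * sp[3] - cen[3]
  r2 <- outer(outer(ax^2, ay^2, "+"), az^2, "+")
  vol <- array(-1000, dims)
  vol[r2 <= (R + 8)^2] <- spec$background_hu          # scalp + brain
  vol[r2 <= (R + 4)^2 & r2 > R^2] <- spec$skull_hu    # skull shell
  rm(r2)

  # ---- painting helpers (voxel centers at (i-1)*spacing, world frame) ----
  box_grid <- function(lo, hi) {
    i0 <- pmax(1L, as.integer(floor(lo / sp)) + 1L)
    i1 <- pmin(dims, as.integer(ceiling(hi / sp)) + 1L)
    if (any(i0 > i1)) return(NULL)
    g <- as.matrix(expand.grid(x = i0[1]:i1[1], y = i0[2]:i1[2],
                               z = i0[3]:i1[3]))
    list(idx = g[, 1] + (g[, 2] - 1L) * nx + (g[, 3] - 1L) * nx * ny,
         w = sweep(g - 1, 2, sp, "*"))
  }
  capsule_idx <- function(p0, p1, radius, flat = FALSE) {
    lo <- pmin(p0, p1) - radius; hi <- pmax(p0, p1) + radius
    bg <- box_grid(lo, hi)
    if (is.null(bg)) return(integer())
    u <- p1 - p0; L <- sqrt(sum(u^2))
    if (L < 1e-9) { a <- rep(0, nrow(bg$w)); u <- c(1, 0, 0) } else {
      u <- u / L
      a <- as.vector(sweep(bg$w, 2, p0) %*% u)
    }
    ac <- pmin(pmax(a, 0), L)
    dp <- bg$w - (matrix(p0, nrow(bg$w), 3, byrow = TRUE) + outer(ac, u))
    inside <- rowSums(dp^2) <= radius^2
    if (flat) inside <- inside & a >= 0 & a <= L
    bg$idx[inside]
  }
  disc_idx <- function(center, normal, diameter, thickness) {
    half <- diameter / 2 + thickness
    bg <- box_grid(center - half, center + half)
    if (is.null(bg)) return(integer())
    w <- sweep(bg$w, 2, center)
    axial <- as.vector(w %*% normal)
    rad2 <- rowSums(w^2) - axial^2
    idx <- bg$idx[abs(axial) <= thickness / 2 & rad2 <= (diameter / 2)^2]
    # a sub-voxel-thick slab can miss every voxel center at coarse spacing:
    # always include the voxels crossed by the disc's mid-plane
    tb <- .tangent_basis(normal)
    step <- 0.35 * min(sp)
    uv <- as.matrix(expand.grid(seq(-diameter / 2, diameter / 2, by = step),
                                seq(-diameter / 2, diameter / 2, by = step)))
    uv <- uv[rowSums(uv^2) <= (diameter / 2)^2, , drop = FALSE]
    pts <- matrix(center, nrow(uv), 3, byrow = TRUE) +
      uv[, 1] %o% tb$e1 + uv[, 2] %o% tb$e2
    vi <- round(sweep(pts, 2, sp, "/")) + 1
    keep <- vi[, 1] >= 1 & vi[, 1] <= dims[1] & vi[, 2] >= 1 &
      vi[, 2] <= dims[2] & vi[, 3] >= 1 & vi[, 3] <= dims[3]
    vi <- vi[keep, , drop = FALSE]
    unique(c(idx, vi[, 1] + (vi[, 2] - 1) * nx + (vi[, 3] - 1) * nx * ny))
  }
  # 6-connected voxel chain along a segment: guarantees thin structures
  # (wires, stitches) are painted even when their radius is below the voxel
  # size, and never fragment under 6-connectivity
  chain_idx <- function(p0, p1) {
    L <- sqrt(sum((p1 - p0)^2))
    ns <- max(2L, as.integer(ceiling(L / (0.4 * min(sp)))) + 1L)
    vx <- vapply(seq(0, 1, length.out = ns), function(t)
      pmin(dims, pmax(1L, as.integer(round((p0 + (p1 - p0) * t) / sp)) + 1L)),
      integer(3))
    out <- list(vx[, 1])
    cur <- vx[, 1]
    for (k in 2:ns) {
      v <- vx[, k]
      for (axd in 1:3) {
        while (cur[axd] != v[axd]) {
          cur[axd] <- cur[axd] + sign(v[axd] - cur[axd])
          out[[length(out) + 1]] <- cur
        }
      }
    }
    m <- do.call(rbind, out)
    unique(m[, 1] + (m[, 2] - 1L) * nx + (m[, 3] - 1L) * nx * ny)
  }
  tube_idx <- function(p0, p1, radius)
    unique(c(capsule_idx(p0, p1, radius), chain_idx(p0, p1)))
  sphere_idx <- function(center, radius) {
    bg <- box_grid(center - radius, center + radius)
    if (is.null(bg)) return(integer())
    bg$idx[rowSums(sweep(bg$w, 2, center)^2) <= radius^2]
  }
  idx_centroid <- function(idx) {
    co <- arrayInd(idx, dims) - 1
    colMeans(sweep(co, 2, sp, "*"))
  }

  objects <- list()
  metal_idx <- list()                   # painted at the end, in one pass
  obj_pts <- matrix(numeric(0), 0, 3)   # sample points for clearance checks
  add_object <- function(idx, class, geometry, pts) {
    if (length(idx) == 0)
      stop("phantom object '", geometry, "' does not fit in the grid")
    metal_idx[[length(metal_idx) + 1]] <<- idx
    ctr <- idx_centroid(idx)
    objects[[length(objects) + 1]] <<- data.frame(
      object_id = length(objects) + 1L, class = class,
      x_mm = ctr[1], y_mm = ctr[2], z_mm = ctr[3], geometry = geometry,
      stringsAsFactors = FALSE)
    obj_pts <<- rbind(obj_pts, pts)
  }
  clearance_ok <- function(pts, min_dist) {
    if (nrow(obj_pts) == 0) return(TRUE)
    for (i in seq_len(nrow(pts))) {
      d2 <- rowSums(sweep(obj_pts, 2, pts[i, ])^2)
      if (min(d2) < min_dist^2) return(FALSE)
    }
    TRUE
  }

  # ---- electrode arrays on the brain-surface sphere ----
  pitch <- spec$electrode_spacing
  geo_point <- function(cdir, basis, ox, oy) {
    v <- ox * basis$e1 + oy * basis$e2
    s <- sqrt(sum(v^2))
    if (s < 1e-9) return(cdir)
    cos(s / R) * cdir + sin(s / R) * v / s
  }
  electrode_pos <- matrix(numeric(0), 0, 3)
  arrays <- c(lapply(spec$grids, function(g)
                list(kind = sprintf("grid_%dx%d", g[1], g[2]),
                     off = as.matrix(expand.grid(
                       (seq_len(g[1]) - (g[1] + 1) / 2) * pitch,
                       (seq_len(g[2]) - (g[2] + 1) / 2) * pitch)))),
              lapply(spec$strips, function(ns)
                list(kind = sprintf("strip_%d", ns),
                     off = cbind((seq_len(ns) - (ns + 1) / 2) * pitch, 0))))
  for (arr in arrays) {
    placed <- FALSE
    for (try in seq_len(400)) {
      cdir <- .runit()
      basis <- .tangent_basis(cdir, stats::runif(1, 0, 2 * pi))
      dirs <- t(apply(arr$off, 1, function(o)
        geo_point(cdir, basis, o[1], o[2])))
      pos <- sweep(dirs * R, 2, cen, "+")
      ok <- TRUE
      if (nrow(electrode_pos) > 0) {
        for (i in seq_len(nrow(pos))) {
          d2 <- rowSums(sweep(electrode_pos, 2, pos[i, ])^2)
          if (min(d2) < (0.8 * pitch)^2) { ok <- FALSE; break }
        }
      }
      if (ok) {
        for (i in seq_len(nrow(pos)))
          add_object(disc_idx(pos[i, ], dirs[i, ], spec$electrode_diameter,
                              spec$electrode_thickness),
                     "ECOG", arr$kind, matrix(pos[i, ], 1))
        electrode_pos <- rbind(electrode_pos, pos)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("cannot place electrode array '", arr$kind,
           "' on the head without collisions")
  }
  # deliberately overlapped electrode pairs (fuse into one cluster)
  if (spec$overlap_electrode_pairs > 0) {
    for (p in seq_len(spec$overlap_electrode_pairs)) {
      base <- electrode_pos[sample.int(nrow(electrode_pos), 1), ]
      ndir <- (base - cen) / sqrt(sum((base - cen)^2))
      tb <- .tangent_basis(ndir, stats::runif(1, 0, 2 * pi))
      shift <- 0.45 * spec$electrode_diameter * tb$e1 +
        0.3 * spec$electrode_thickness * ndir
      add_object(disc_idx(base + shift, ndir, spec$electrode_diameter,
                          spec$electrode_thickness),
                 "ECOG", "overlap_electrode", matrix(base + shift, 1))
    }
  }

  # ---- depth-electrode arrays along straight insertion lines ----
  for (da in spec$depth_arrays) {
    nc <- da[1]; clen <- da[2]; cdia <- da[3]; cpitch <- da[4]
    if (R - 6 - (nc - 1) * cpitch < 4)
      stop("phantom object 'depth_array' does not fit in the grid (too many ",
           "contacts for the head radius)")
    ddir <- .runit()
    centers <- lapply(seq_len(nc) - 1, function(j)
      cen + (R - 6 - j * cpitch) * ddir)
    if (spec$depth_fused)
      metal_idx[[length(metal_idx) + 1]] <-
        capsule_idx(centers[[1]] + ddir * clen / 2,
                    centers[[nc]] - ddir * clen / 2, 0.4)
    for (j in seq_len(nc)) {
      p0 <- centers[[j]] - ddir * clen / 2
      p1 <- centers[[j]] + ddir * clen / 2
      add_object(capsule_idx(p0, p1, cdia / 2, flat = TRUE), "DEPTH",
                 "depth_contact", matrix(centers[[j]], 1))
    }
  }

  # ---- wires: smooth random tubes partly exiting the head ----
  in_grid <- function(p) all(p >= 2) && all(p <= (dims - 1) * sp - 2)
  for (w in seq_len(spec$n_wires)) {
    done <- FALSE
    for (try in seq_len(60)) {
      sdir <- .runit()
      pos <- cen + (R + 9.5) * sdir
      tb <- .tangent_basis(sdir, stats::runif(1, 0, 2 * pi))
      d <- tb$e1 * 0.8 + sdir * 0.45
      d <- d / sqrt(sum(d^2))
      len <- stats::runif(1, 30, 70)
      pts <- matrix(pos, 1)
      for (s in seq_len(ceiling(len / 2))) {
        d <- d + stats::rnorm(3, 0, 0.28)
        d <- d / sqrt(sum(d^2))
        cand <- pos + 2 * d
        rr <- sqrt(sum((cand - cen)^2))
        if (rr < R + 6.5) cand <- cen + (cand - cen) * (R + 6.5) / rr
        if (!in_grid(cand)) break
        pos <- cand
        pts <- rbind(pts, pos)
      }
      if (nrow(pts) < 6) next
      if (!clearance_ok(pts, 4)) next
      dia <- stats::runif(1, 0.8, 1.3)
      idx <- integer()
      for (s in seq_len(nrow(pts) - 1))
        idx <- c(idx, tube_idx(pts[s, ], pts[s + 1, ], dia / 2))
      add_object(unique(idx), "NON_ELECTRODE", "wire", pts)
      done <- TRUE
      break
    }
    if (!done) stop("cannot place wire ", w, " without collisions")
  }

  # ---- stitches: short bent segments in/above the scalp ----
  for (s in seq_len(spec$n_stitches)) {
    done <- FALSE
    for (try in seq_len(120)) {
      rr <- if (stats::runif(1) < 0.15) stats::runif(1, R + 11, R + 14)
            else stats::runif(1, R + 4.5, R + 10.5)
      pos <- cen + rr * .runit()
      u1 <- .runit()
      ang <- stats::runif(1, 0.4, 1.2)
      tb <- .tangent_basis(u1, stats::runif(1, 0, 2 * pi))
      u2 <- cos(ang) * u1 + sin(ang) * tb$e1
      total <- stats::runif(1, 2, 5)
      p0 <- pos - u1 * total / 2
      p1 <- pos + u2 * total / 2
      pts <- rbind(p0, pos, p1)
      if (!all(apply(pts, 1, in_grid))) next
      if (!clearance_ok(pts, 4.5)) next
      dia <- stats::runif(1, 0.5, 0.9)
      idx <- unique(c(tube_idx(p0, pos, dia / 2),
                      tube_idx(pos, p1, dia / 2)))
      add_object(idx, "NON_ELECTRODE", "stitch", pts)
      done <- TRUE
      break
    }
    if (!done) stop("cannot place stitch ", s, " without collisions")
  }

  # ---- screws: shaft + head in the skull ----
  for (s in seq_len(spec$n_screws)) {
    done <- FALSE
    for (try in seq_len(120)) {
      sdir <- .runit()
      outer_p <- cen + (R + 4.5) * sdir
      L <- stats::runif(1, 3, 7)
      pts <- rbind(outer_p, outer_p - sdir * L)
      if (!all(apply(pts, 1, in_grid))) next
      if (!clearance_ok(pts, 5.5)) next
      shaft_d <- stats::runif(1, 1.5, 2.5)
      head_d <- stats::runif(1, 2.5, 4)
      idx <- unique(c(tube_idx(outer_p, outer_p - sdir * L, shaft_d / 2),
                      sphere_idx(outer_p, head_d / 2)))
      add_object(idx, "NON_ELECTRODE", "screw", pts)
      done <- TRUE
      break
    }
    if (!done) stop("cannot place screw ", s, " without collisions")
  }

  # ---- acquisition: paint metal, PSF blur, HU ceiling, noise ----
  vol[unlist(metal_idx)] <- spec$metal_hu
  if (spec$psf_sigma > 0)
    vol <- .cpp_gaussian_blur(vol, dims, spec$psf_sigma / sp)
  if (is.finite(spec$clip_hu)) vol[vol > spec$clip_hu] <- spec$clip_hu
  if (spec$noise_sigma > 0)
    vol <- vol + stats::rnorm(length(vol), 0, spec$noise_sigma)
  dim(vol) <- dims

  truth <- do.call(rbind, objects)
  list(volume = ct_volume(vol, sp,
                          source_id = sprintf("phantom_seed%d", spec$seed)),
       truth = truth)
}

#' Match classified detections against phantom ground truth
#'
#' Greedy nearest-centroid one-to-one matching within `tolerance_mm`,
#' per electrode class. Unmatched truth electrodes count as false negatives;
#' unmatched electrode-class detections as false positives.
#'
#' @param detections data.frame with `predicted_class`, `centroid_x_mm`,
#'   `centroid_y_mm`, `centroid_z_mm` (e.g. a classified feature table).
#' @param truth ground-truth data.frame from [generate_phantom()].
#' @param tolerance_mm matching radius (default 2, half an electrode
#'   diameter).
#' @param electrode_classes classes scored as detections.
#' @return list with `per_class` (data.frame: class, tp, fn, fp,
#'   sensitivity) and `matches` (detection row, object_id, distance).
#' @export
match_detections <- function(detections, truth, tolerance_mm = 2.0,
                             electrode_classes = c("ECOG", "DEPTH")) {
  if (tolerance_mm <= 0) stop("tolerance_mm must be > 0")
  matches <- NULL
  per_class <- NULL
  for (cl in electrode_classes) {
    det <- which(detections$predicted_class == cl)
    tru <- which(truth$class == cl)
    dm <- matrix(Inf, length(det), length(tru))
    if (length(det) && length(tru)) {
      dc <- as.matrix(detections[det, c("centroid_x_mm", "centroid_y_mm",
                                        "centroid_z_mm")])
      tc <- as.matrix(truth[tru, c("x_mm", "y_mm", "z_mm")])
      for (j in seq_along(tru))
        dm[, j] <- sqrt(rowSums(sweep(dc, 2, tc[j, ])^2))
    }
    tp <- 0L
    while (length(dm) && min(dm) <= tolerance_mm) {
      w <- which(dm == min(dm), arr.ind = TRUE)[1, , drop = FALSE]
      matches <- rbind(matches, data.frame(
        detection_row = det[w[1]], object_id = truth$object_id[tru[w[2]]],
        distance_mm = dm[w[1], w[2]], class = cl, stringsAsFactors = FALSE))
      dm[w[1], ] <- Inf
      dm[, w[2]] <- Inf
      tp <- tp + 1L
    }
    fn <- length(tru) - tp
    fp <- length(det) - tp
    per_class <- rbind(per_class, data.frame(
      class = cl, tp = tp, fn = fn, fp = fp,
      sensitivity = if (length(tru)) 100 * tp / length(tru) else NA_real_,
      stringsAsFactors = FALSE))
  }
  list(per_class = per_class, matches = matches)
}

#' Assign true classes to clusters by nearest ground-truth centroid
#'
#' Each cluster takes the class of the nearest truth object within
#' `tolerance_mm`; clusters matching nothing (e.g. fused electrode pairs,
#' whose merged centroid sits between the two truth discs) are labeled
#' `NON_ELECTRODE`.
#'
#' @param tab a `feature_table`.
#' @param truth ground truth from [generate_phantom()].
#' @param tolerance_mm matching radius (default 2).
#' @return `tab` with `true_class` filled in.
#' @export
assign_true_classes <- function(tab, truth, tolerance_mm = 2.0) {
  if (nrow(tab) == 0) return(tab)
  tc <- as.matrix(truth[, c("x_mm", "y_mm", "z_mm")])
  cc <- as.matrix(tab[, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")])
  cls <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    d <- sqrt(rowSums(sweep(tc, 2, cc[i, ])^2))
    j <- which.min(d)
    cls[i] <- if (d[j] <= tolerance_mm) truth$class[j] else "NON_ELECTRODE"
  }
  tab$true_class <- cls
  tab
}

#' Run the detection pipeline on a phantom and return a labeled table
#'
#' Convenience wrapper: generate (or accept) a phantom, resample to the
#' target spacing, threshold, label, extract features and assign true
#' classes from the ground truth.
#'
#' @param spec a [phantom_spec()] or the result of [generate_phantom()].
#' @param target_spacing,hu_threshold,axis_mode pipeline parameters
#'   (paper defaults).
#' @param label_tolerance_mm truth-matching radius for class assignment.
#' @param patient_id stored in the table; default `phantom_seed<seed>`.
#' @return list with `features` (labeled `feature_table`), `truth`, and
#'   `n_clusters`.
#' @export
phantom_pipeline <- function(spec, target_spacing = 0.5, hu_threshold = 2500,
                             axis_mode = "moment", label_tolerance_mm = 2.0,
                             patient_id = NULL) {
  ph <- if (inherits(spec, "phantom_spec")) generate_phantom(spec) else spec
  if (is.null(patient_id)) patient_id <- ph$volume$source_id
  iso <- resample_isotropic(ph$volume, target_spacing)
  lab <- label_clusters(threshold_metal(iso, hu_threshold))
  tab <- compute_feature_table(lab, axis_mode, patient_id)
  tab <- assign_true_classes(tab, ph$truth, label_tolerance_mm)
  list(features = tab, truth = ph$truth, n_clusters = lab$n_clusters)
}
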