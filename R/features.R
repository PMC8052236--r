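# The six geometric descriptors. Axis lengths follow the moment-equivalent
# ellipsoid convention: per principal direction, length = 2*sqrt(5*lambda)
# where lambda is an eigenvalue of the voxel-position covariance (population
# normalization) after adding the voxel-spread correction 1/12 to each
# diagonal term. The correction equals the second moment of a unit cube about
# its center, so a single voxel gets the axes of its continuous cube
# (2*sqrt(5/12) = 1.2910) and degenerate flat/linear clusters keep strictly
# positive axes. An "extent" mode measuring the cluster's support along the
# same principal directions is provided for sensitivity analysis.

.feature_names <- c("volume", "primary_axis", "secondary_axis",
                    "tertiary_axis", "circularity", "cylinder_similarity")

#' Principal axis lengths of a voxel cluster
#'
#' @param cluster_voxels n x 3 matrix of voxel indices (any consistent
#'   origin; integer grid steps assumed).
#' @param axis_mode `"moment"` (default): axis lengths of the
#'   moment-equivalent ellipsoid, `2*sqrt(5*lambda)`; `"extent"`: the
#'   cluster's extent along the same principal directions (center spread plus
#'   the projected width of one voxel cube).
#' @return numeric length-3: primary >= secondary >= tertiary, in voxel units.
#' @export
principal_axis_lengths <- function(cluster_voxels,
                                   axis_mode = c("moment", "extent")) {
  axis_mode <- match.arg(axis_mode)
  v <- matrix(as.numeric(cluster_voxels), ncol = 3)
  if (nrow(v) < 1) stop("empty cluster")
  ctr <- colMeans(v)
  vc <- sweep(v, 2, ctr)
  cov <- crossprod(vc) / nrow(v) + diag(1 / 12, 3)
  eg <- eigen(cov, symmetric = TRUE)
  if (axis_mode == "moment") {
    len <- 2 * sqrt(5 * pmax(eg$values, 0))
  } else {
    len <- vapply(1:3, function(k) {
      e <- eg$vectors[, k]
      p <- vc %*% e
      (max(p) - min(p)) + sum(abs(e))
    }, 0)
  }
  sort(len, decreasing = TRUE)
}

#' Circularity of a cluster
#'
#' Ratio of primary to secondary axis length; 1 for an ideal disc, well
#' above 1 for elongated objects such as wires.
#'
#' @param primary,secondary axis lengths, `primary >= secondary > 0`.
#' @return dimensionless ratio >= 1.
#' @export
circularity <- function(primary, secondary) {
  if (any(secondary <= 0)) stop("secondary axis length must be positive")
  if (any(primary < secondary)) stop("primary must be >= secondary")
  primary / secondary
}

#' Cylinder similarity of a cluster
#'
#' Volume of the cylinder with diameter equal to the mean of primary and
#' secondary axis lengths and height equal to the tertiary axis length,
#' divided by the cluster's voxel count:
#' `((p + s) / 4)^2 * pi * t / V`. Equal to 1 for an ideal flattened
#' cylinder measured with extent axes; about 1.61 for a solid disc measured
#' with moment axes.
#'
#' @param primary,secondary,tertiary axis lengths (> 0, voxel units).
#' @param volume cluster voxel count (>= 1).
#' @return dimensionless ratio > 0.
#' @export
cylinder_similarity <- function(primary, secondary, tertiary, volume) {
  if (any(primary <= 0) || any(secondary <= 0) || any(tertiary <= 0))
    stop("axis lengths must be positive")
  if (any(volume < 1)) stop("volume must be >= 1")
  ((primary + secondary) / 4)^2 * pi * tertiary / volume
}

#' Compute the feature table for all clusters of a labeling
#'
#' One row per cluster: voxel-count volume, the three principal axis lengths
#' (resampled-voxel units), circularity, cylinder similarity, and the
#' centroid in voxel and world coordinates.
#'
#' @param labeling a `cluster_labeling`.
#' @param axis_mode `"moment"` (default) or `"extent"`, see
#'   [principal_axis_lengths()].
#' @param patient_id free-text provenance tag stored per row.
#' @return a `feature_table` (data.frame) with columns `patient_id`,
#'   `cluster_id`, the six features, `centroid_x_mm`, `centroid_y_mm`,
#'   `centroid_z_mm` and `true_class` (NA until assigned).
#' @export
compute_feature_table <- function(labeling, axis_mode = c("moment", "extent"),
                                  patient_id = "") {
  axis_mode <- match.arg(axis_mode)
  if (!inherits(labeling, "cluster_labeling")) stop("not a cluster_labeling")
  K <- labeling$n_clusters
  if (K == 0) return(empty_feature_table())
  idx <- which(labeling$labels > 0)
  lab <- labeling$labels[idx]
  co <- arrayInd(idx, dim(labeling$labels)) - 1  # 0-based voxel coords
  storage.mode(co) <- "double"
  n <- tabulate(lab, K)
  # sufficient statistics per cluster
  s1 <- rowsum(co, lab)
  s2 <- rowsum(cbind(co^2, co[, 1] * co[, 2], co[, 1] * co[, 3],
                     co[, 2] * co[, 3]), lab)
  mu <- s1 / n
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    cxx <- s2[k, 1] / n[k] - mu[k, 1]^2 + 1 / 12
    cyy <- s2[k, 2] / n[k] - mu[k, 2]^2 + 1 / 12
    czz <- s2[k, 3] / n[k] - mu[k, 3]^2 + 1 / 12
    cxy <- s2[k, 4] / n[k] - mu[k, 1] * mu[k, 2]
    cxz <- s2[k, 5] / n[k] - mu[k, 1] * mu[k, 3]
    cyz <- s2[k, 6] / n[k] - mu[k, 2] * mu[k, 3]
    C <- matrix(c(cxx, cxy, cxz, cxy, cyy, cyz, cxz, cyz, czz), 3, 3)
    eg <- eigen(C, symmetric = TRUE)
    if (axis_mode == "moment") {
      len <- sort(2 * sqrt(5 * pmax(eg$values, 0)), decreasing = TRUE)
    } else {
      vc <- sweep(co[lab == k, , drop = FALSE], 2, mu[k, ])
      len <- sort(vapply(1:3, function(j) {
        e <- eg$vectors[, j]
        p <- vc %*% e
        (max(p) - min(p)) + sum(abs(e))
      }, 0), decreasing = TRUE)
    }
    rows[[k]] <- c(len, n[k])
  }
  len <- do.call(rbind, rows)
  cen_mm <- cbind(mu, 1) %*% t(labeling$affine)
  tab <- data.frame(
    patient_id = patient_id,
    cluster_id = seq_len(K),
    volume = n,
    primary_axis = len[, 1],
    secondary_axis = len[, 2],
    tertiary_axis = len[, 3],
    circularity = len[, 1] / len[, 2],
    cylinder_similarity = ((len[, 1] + len[, 2]) / 4)^2 * pi * len[, 3] / n,
    centroid_x_mm = cen_mm[, 1],
    centroid_y_mm = cen_mm[, 2],
    centroid_z_mm = cen_mm[, 3],
    true_class = NA_character_,
    stringsAsFactors = FALSE)
  class(tab) <- c("feature_table", "data.frame")
  tab
}

empty_feature_table <- function() {
  tab <- data.frame(patient_id = character(), cluster_id = integer(),
                    volume = integer(), primary_axis = numeric(),
                    secondary_axis = numeric(), tertiary_axis = numeric(),
                    circularity = numeric(), cylinder_similarity = numeric(),
                    centroid_x_mm = numeric(), centroid_y_mm = numeric(),
                    centroid_z_mm = numeric(), true_class = character(),
                    stringsAsFactors = FALSE)
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Write / read a feature table as CSV
#'
#' @param tab a `feature_table`.
#' @param path CSV file path.
#' @return `path` (write) or a `feature_table` (read).
#' @export
write_feature_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "cluster_id", .feature_names,
            "centroid_x_mm", "centroid_y_mm", "centroid_z_mm")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("feature CSV missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(tab$true_class)) tab$true_class <- NA_character_
  tab$patient_id <- as.character(tab$patient_id)
  tab$true_class <- as.character(tab$true_class)
  class(tab) <- c("feature_table", "data.frame")
  tab
}
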