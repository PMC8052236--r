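#' Threshold a CT volume at the metal radiodensity
#'
#' Marks voxels whose HU value strictly exceeds `hu_threshold`. The paper's
#' metal threshold of 2500 HU sits above compact bone, so the mask retains
#' electrodes, wires, stitches, screws and dental work but no tissue.
#'
#' @param vol a `ct_volume`, typically already resampled to 0.5 mm.
#' @param hu_threshold threshold in HU (default 2500); strict inequality.
#' @return a `binary_volume`: list with logical `mask`, `spacing`, `affine`.
#' @export
threshold_metal <- function(vol, hu_threshold = 2500) {
  validate_ct_volume(vol)
  mask <- vol$values > hu_threshold
  structure(list(mask = mask, spacing = vol$spacing, affine = vol$affine),
            class = "binary_volume")
}

#' Label 6-connected voxel clusters
#'
#' Connected components under face adjacency only (6-connectivity): voxels
#' touching only through an edge or corner belong to different clusters.
#' Clusters are numbered by the position of their first voxel in the grid's
#' linear scan order, so labels are deterministic across runs and platforms.
#'
#' @param binary a `binary_volume`.
#' @return a `cluster_labeling`: list with integer array `labels`
#'   (0 = background), `n_clusters`, `spacing`, `affine`.
#' @export
label_clusters <- function(binary) {
  if (!inherits(binary, "binary_volume")) stop("not a binary_volume")
  res <- .cpp_label6(as.logical(binary$mask), as.integer(dim(binary$mask)))
  structure(list(labels = res$labels, n_clusters = res$n_clusters,
                 spacing = binary$spacing, affine = binary$affine),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf("cluster_labeling: %d clusters on a %s grid\n", x$n_clusters,
              paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}
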