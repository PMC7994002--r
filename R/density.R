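#' Nuclei heat map
#'
#' Converts blob centres to per-voxel counts at (typically downsampled) atlas
#' shape: each centre is multiplied by `scale`, rounded to the nearest voxel,
#' and counted. Out-of-bounds blobs are dropped (their number is recorded in
#' the `n_dropped` attribute).
#'
#' @param blobs blob data.frame (`plane`, `row`, `col` in voxels of the
#'   source image).
#' @param scale length-3 factor from blob coordinates to heat-map voxels.
#' @param shape heat-map shape.
#' @return integer array of counts with attribute `n_dropped`.
#' @export
nuclei_heatmap <- function(blobs, scale = c(1, 1, 1), shape) {
  stopifnot(all(scale > 0), length(shape) == 3L)
  hm <- array(0L, shape)
  if (nrow(blobs)) {
    # map centre coordinates between the two voxel grids, then round
    i <- round((blobs$plane - 0.5) * scale[1] + 0.5)
    j <- round((blobs$row - 0.5) * scale[2] + 0.5)
    k <- round((blobs$col - 0.5) * scale[3] + 0.5)
    ok <- i >= 1 & i <= shape[1] & j >= 1 & j <= shape[2] & k >= 1 & k <= shape[3]
    idx <- cbind(i[ok], j[ok], k[ok])
    for (t in seq_len(nrow(idx))) {
      hm[idx[t, 1], idx[t, 2], idx[t, 3]] <- hm[idx[t, 1], idx[t, 2], idx[t, 3]] + 1L
    }
    attr(hm, "n_dropped") <- sum(!ok)
  } else {
    attr(hm, "n_dropped") <- 0L
  }
  hm
}

#' Per-label nuclei counts, volumes, and densities
#'
#' Sums heat-map counts within each label mask; label volume is voxel count
#' times voxel volume converted to mm^3; density is count per mm^3. The
#' density CV is sigma/mu of the per-voxel counts within the label
#' (population sd), a within-label homogeneity measure.
#'
#' @param heatmap count array from [nuclei_heatmap()].
#' @param labels co-shaped `label_volume` or integer array.
#' @param spacing heat-map voxel spacing in micrometres.
#' @return data.frame keyed by `label_id` with `count`, `volume_mm3`,
#'   `density_per_mm3`, `density_cv`; ontology names joined when available.
#' @export
per_label_stats <- function(heatmap, labels, spacing = NULL) {
  lab <- vol_data(labels)
  stopifnot(identical(dim(heatmap), dim(lab)))
  sp <- spacing %||% vol_spacing(labels)
  vox_mm3 <- prod(sp) * 1e-9  # um^3 -> mm^3
  ids <- label_ids(lab)
  rows <- lapply(ids, function(id) {
    sel <- lab == id
    counts <- heatmap[sel]
    n <- length(counts)
    mu <- mean(counts)
    sg <- sqrt(mean((counts - mu)^2))
    data.frame(label_id = id, count = sum(counts), n_voxels = n,
               volume_mm3 = n * vox_mm3,
               density_per_mm3 = sum(counts) / (n * vox_mm3),
               density_cv = if (mu > 0) sg / mu else NA_real_)
  })
  df <- do.call(rbind, rows)
  ont <- if (is_label_volume(labels)) labels$ontology else NULL
  if (!is.null(ont)) {
    df$name <- ont$name[match(df$label_id, ont$id)]
  }
  df
}

#' DBSCAN clustering parameters
#'
#' `min_samples` defaults to the `2 * ndim` heuristic (6 for 3D point
#' clouds); `eps` defaults to a conservative 20 um, at the lower edge of the
#' k-distance elbow region for nuclear point clouds at this resolution.
#'
#' @param eps neighbourhood radius in micrometres.
#' @param min_samples minimum neighbourhood size (self included) for a core
#'   point.
#' @param ndim dimensionality used by the default rule.
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(eps = 20, min_samples = dbscan_min_samples(ndim),
                           ndim = 3L) {
  stopifnot(eps > 0, min_samples >= 1)
  structure(list(eps = eps, min_samples = as.integer(min_samples)),
            class = "cluster_params")
}

#' The 2*ndim rule for DBSCAN min_samples
#' @param ndim point-cloud dimensionality.
#' @return `2 * ndim`.
#' @export
dbscan_min_samples <- function(ndim = 3L) 2L * as.integer(ndim)

#' Per-label nuclei clustering quality
#'
#' Assigns each blob to the label at its rounded heat-map voxel (the same
#' rule used for counting, so counts and clustering agree), converts centres
#' to micrometres, and runs DBSCAN independently within every label (a
#' cluster can never span labels). Points that cannot be clustered are
#' noise — isolated nuclei, which accumulate where labels are misaligned
#' with the underlying tissue.
#'
#' @param blobs blob data.frame.
#' @param labels `label_volume` or integer array (at blob-coordinate scale).
#' @param spacing voxel spacing in micrometres.
#' @param params [cluster_params()].
#' @return data.frame per label (`label_id`, `n_nuclei`, `n_clusters`,
#'   `n_noise`) with attributes `total_clusters`, `total_noise`.
#' @export
cluster_label_nuclei <- function(blobs, labels, spacing = NULL,
                                 params = cluster_params()) {
  lab <- vol_data(labels)
  sp <- spacing %||% vol_spacing(labels)
  d <- dim(lab)
  i <- pmin(pmax(round(blobs$plane), 1L), d[1])
  j <- pmin(pmax(round(blobs$row), 1L), d[2])
  k <- pmin(pmax(round(blobs$col), 1L), d[3])
  blob_label <- lab[cbind(i, j, k)]
  ids <- label_ids(lab)
  rows <- lapply(ids, function(id) {
    sel <- which(blob_label == id)
    if (!length(sel)) {
      return(data.frame(label_id = id, n_nuclei = 0L, n_clusters = 0L,
                        n_noise = 0L))
    }
    pts <- cbind(blobs$plane[sel] * sp[1], blobs$row[sel] * sp[2],
                 blobs$col[sel] * sp[3])
    cl <- cpp_dbscan(pts, params$eps, params$min_samples)
    data.frame(label_id = id, n_nuclei = length(sel),
               n_clusters = length(setdiff(unique(cl), 0L)),
               n_noise = sum(cl == 0L))
  })
  df <- do.call(rbind, rows)
  attr(df, "total_clusters") <- sum(df$n_clusters)
  attr(df, "total_noise") <- sum(df$n_noise)
  df
}

#' k-nearest-neighbour distances for eps selection
#'
#' Distance of every point to its k-th nearest neighbour (micrometres),
#' sorted non-decreasing; the elbow of this curve is the usual guide for the
#' DBSCAN `eps` parameter (k defaults to `2 * ndim - 1 = 5`).
#'
#' @param points matrix or blob data.frame of coordinates (voxels).
#' @param k neighbour rank.
#' @param spacing voxel spacing in micrometres.
#' @return sorted numeric vector of k-NN distances.
#' @export
knn_elbow_distances <- function(points, k = 5L, spacing = c(1, 1, 1)) {
  if (is.data.frame(points)) {
    points <- cbind(points$plane, points$row, points$col)
  }
  if (nrow(points) <= k) stop("need more than k points")
  pts <- sweep(points, 2, spacing[seq_len(ncol(points))], `*`)
  sort(cpp_knn_kth(pts, as.integer(k)))
}
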