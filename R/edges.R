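#' Parameters for anatomical edge-map generation
#'
#' The edge detector is a Gaussian blur (broad sigma, default 5 voxels, so
#' only gross anatomical boundaries such as the cortex or basal ganglia
#' survive) followed by a 3-point Laplacian and a morphological zero-crossing
#' detector. Background suppression either unions the foreground threshold
#' with the label mask (`"labels_union_threshold"`, the default, which fills
#' unlabeled holes such as ventricles) or relies on the threshold alone
#' (`"threshold_only"`, used when ventricles are themselves labeled).
#'
#' @param gaussian_sigma Gaussian sigma in voxels (>= 0).
#' @param laplacian_size Laplacian operator size; odd, >= 3 (the 3-point
#'   stencil is the only size currently implemented).
#' @param background_strategy `"labels_union_threshold"` or `"threshold_only"`.
#' @return an `edge_map_params` list.
#' @export
edge_map_params <- function(gaussian_sigma = 5, laplacian_size = 3L,
                            background_strategy = c("labels_union_threshold",
                                                    "threshold_only")) {
  background_strategy <- match.arg(background_strategy)
  stopifnot(gaussian_sigma >= 0, laplacian_size >= 3L, laplacian_size %% 2L == 1L)
  structure(list(gaussian_sigma = gaussian_sigma,
                 laplacian_size = as.integer(laplacian_size),
                 background_strategy = background_strategy),
            class = "edge_map_params")
}

#' Morphological zero-crossing detector
#'
#' Flags voxels where the neighbourhood erosion and dilation of a signed
#' scalar field disagree in sign — the discrete zero crossings of, e.g., a
#' Laplacian-of-Gaussian response.
#'
#' @param signed numeric 3D array.
#' @param connectivity 6 (face neighbours + centre, the Euclidean ball of
#'   radius 1; default) or 26 (full 3x3x3 box).
#' @param tol relative magnitude (of the array maximum) below which values
#'   count as zero, so floating-point ripple in flat regions does not
#'   register as a crossing.
#' @return logical edge map.
#' @export
zero_crossings <- function(signed, connectivity = 6L, tol = 1e-10) {
  stopifnot(length(dim(signed)) == 3L, connectivity %in% c(6L, 26L))
  lo <- cpp_minmax3(as.double(signed), dim(signed), connectivity, FALSE)
  hi <- cpp_minmax3(as.double(signed), dim(signed), connectivity, TRUE)
  eps <- tol * max(abs(signed))
  slo <- sign(lo)
  shi <- sign(hi)
  if (is.finite(eps) && eps > 0) {
    slo[abs(lo) <= eps] <- 0
    shi[abs(hi) <= eps] <- 0
  }
  out <- slo != shi
  dim(out) <- dim(signed)
  out
}

#' Anatomical edge map from an intensity volume
#'
#' Smooths the volume with a broad Gaussian, applies the Laplacian, and takes
#' morphological zero crossings, then suppresses responses outside the tissue
#' foreground. The outer surface of the foreground mask is added so the
#' tissue outline itself always appears as an edge (downstream watershed
#' growth then respects the brain outline).
#'
#' @param vol intensity `volume` or 3D array.
#' @param labels optional `label_volume`; required for the default
#'   `labels_union_threshold` background strategy.
#' @param params an [edge_map_params()] list.
#' @return logical edge map, same shape as `vol`.
#' @export
anatomical_edge_map <- function(vol, labels = NULL, params = edge_map_params()) {
  x <- vol_data(vol)
  if (params$background_strategy == "labels_union_threshold" && is.null(labels)) {
    stop("background_strategy 'labels_union_threshold' needs a label volume")
  }
  fg <- threshold_foreground(x, "otsu")
  if (params$background_strategy == "labels_union_threshold") {
    fg <- fg | (vol_data(labels) != 0L)
  }
  # truncate at 8 sigma: at 4 sigma the kernel cut-off leaves ~1e-4-relative
  # ripple in the LoG response whose sign flips register as ghost edge sheets
  sm <- cpp_gauss3d(as.double(x), dim(x), rep(params$gaussian_sigma, 3), 8)
  lap <- cpp_laplace3(sm, dim(x))
  zc <- zero_crossings(array(lap, dim(x)))
  edge <- zc & fg
  if (any(fg)) {
    outer_surface <- fg & !cpp_erode_cross(fg, dim(x), TRUE)
    edge <- edge | outer_surface
  }
  dim(edge) <- dim(x)
  edge
}

#' Label surface voxels
#'
#' Per label, the surface is the label minus its erosion by the face-connected
#' cross; the union over all labels is returned. Equivalently a voxel is a
#' surface voxel iff it is labeled and any face neighbour (or the array
#' border) carries a different value.
#'
#' @param labels `label_volume` or integer array.
#' @return logical array of surface voxels.
#' @export
label_surfaces <- function(labels) {
  lab <- vol_data(labels)
  out <- cpp_label_surfaces(as.integer(lab), dim(lab))
  dim(out) <- dim(lab)
  out
}
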