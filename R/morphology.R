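#' Euclidean distance transform
#'
#' Exact squared (or plain) Euclidean distance from every voxel to the nearest
#' `TRUE` voxel, honouring anisotropic spacing. Voxels of an all-`FALSE`
#' input map to `Inf`.
#'
#' @param feature logical 3D array.
#' @param spacing per-axis physical step (default voxel units).
#' @param squared return squared distances (avoids the square root)?
#' @return numeric array of distances.
#' @export
distance_transform <- function(feature, spacing = c(1, 1, 1), squared = FALSE) {
  stopifnot(is.logical(feature), length(dim(feature)) == 3L)
  d2 <- cpp_edt_sq(feature, dim(feature), as.numeric(spacing))
  if (squared) d2 else sqrt(d2)
}

# Ball-shaped binary morphology, implemented exactly through the distance
# transform: erosion keeps voxels farther than r from background, dilation
# keeps voxels within r of foreground. r is in voxels; voxels outside the
# array are treated as foreground for erosion (masks touching the border are
# not eaten from outside) and background for dilation.
mask_erode_ball <- function(mask, r) {
  if (r <= 0) return(mask)
  if (!any(!mask)) return(mask)
  d2 <- cpp_edt_sq(!mask, dim(mask), c(1, 1, 1))
  out <- mask & (d2 > r * r)
  dim(out) <- dim(mask)
  out
}

mask_dilate_ball <- function(mask, r) {
  if (r <= 0) return(mask)
  if (!any(mask)) return(mask)
  d2 <- cpp_edt_sq(mask, dim(mask), c(1, 1, 1))
  out <- d2 <= r * r
  dim(out) <- dim(mask)
  out
}

mask_open_ball <- function(mask, r) mask_dilate_ball(mask_erode_ball(mask, r), r)
mask_close_ball <- function(mask, r) mask_erode_ball(mask_dilate_ball(mask, r), r)

# Distance-ridge skeleton: voxels whose distance-to-background is a
# 26-neighbourhood local maximum. A medial core that survives erosion of thin
# structures (a 1-voxel sheet is its own ridge).
skeletonize_ridge <- function(mask) {
  if (!any(mask)) return(mask)
  d2 <- cpp_edt_sq(!mask, dim(mask), c(1, 1, 1))
  d2[is.infinite(d2)] <- max(dim(mask))^2  # fully-foreground array
  mx <- cpp_minmax3(d2, dim(mask), 26L, TRUE)
  out <- mask & (d2 >= mx)
  dim(out) <- dim(mask)
  out
}

#' Nearest-label in-painting
#'
#' Assigns every unlabeled voxel of `target` the label of its nearest
#' (spacing-aware Euclidean) labeled voxel. Previously labeled voxels are
#' never changed. Equidistant donors are resolved deterministically to the
#' donor with the lowest linear index.
#'
#' @param labels a `label_volume` (or integer array).
#' @param target logical array of voxels that must come out labeled.
#' @return same type as `labels`.
#' @examples
#' l <- array(0L, c(3, 3, 3)); l[2, 2, 2] <- 7L
#' filled <- in_paint_labels(l, array(TRUE, c(3, 3, 3)))
#' all(filled == 7L)
#' @export
in_paint_labels <- function(labels, target) {
  lab <- vol_data(labels)
  stopifnot(identical(dim(lab), dim(target)))
  if (!any(lab != 0L)) {
    if (any(target)) stop("cannot in-paint: no donor labels present")
    return(labels)
  }
  sp <- vol_spacing(labels)
  out <- cpp_inpaint(as.integer(lab), target, dim(lab), as.numeric(sp))
  dim(out) <- dim(lab)
  with_data(labels, out)
}

#' Volume downsampling (and resampling)
#'
#' Resamples to an arbitrary target shape. Intensity volumes use trilinear
#' interpolation; label volumes use order-0 (nearest neighbour), so no new
#' label values can appear. Spacing is rescaled by the shape ratio. The
#' chunked path splits the output along axis 1 into blocks whose input
#' support is computed independently; it is elementwise identical to the
#' unchunked path because every output voxel is interpolated from the same
#' input coordinates.
#'
#' @param x `volume`, `label_volume`, or 3D array.
#' @param target_shape integer length-3 output shape.
#' @param chunked process the output in blocks along axis 1?
#' @param chunk_planes output planes per block when `chunked`.
#' @return same type as `x`.
#' @export
downsample <- function(x, target_shape, chunked = FALSE, chunk_planes = 16L) {
  target_shape <- as.integer(target_shape)
  stopifnot(length(target_shape) == 3L, all(target_shape >= 1L))
  dat <- vol_data(x)
  order <- if (is_label_volume(x) || is.integer(dat)) 0L else 1L
  d <- dim(dat)
  if (!chunked) {
    out <- cpp_resize3d(as.double(dat), d, target_shape, order)
  } else {
    out <- array(0, target_shape)
    starts <- seq(1L, target_shape[1], by = chunk_planes)
    scale1 <- d[1] / target_shape[1]
    for (s in starts) {
      e <- min(s + chunk_planes - 1L, target_shape[1])
      # input block whose voxels can influence output planes s..e (1-based)
      in_lo <- max(1L, floor((s - 1 + 0.5) * scale1 - 0.5))
      in_hi <- min(d[1], ceiling((e - 1 + 0.5) * scale1 - 0.5) + 2L)
      sub <- dat[in_lo:in_hi, , , drop = FALSE]
      blk <- resize3d_window(sub, c(e - s + 1L, target_shape[2], target_shape[3]),
                             order, c(s - 1L, 0L, 0L), target_shape, d,
                             in_lo - 1L)
      out[s:e, , ] <- blk
    }
  }
  dim(out) <- target_shape
  if (inherits(x, "volume")) {
    new_sp <- x$spacing * d / target_shape
    if (is_label_volume(x)) {
      label_volume(out, spacing = new_sp, origin = x$origin, ontology = x$ontology)
    } else {
      volume(out, spacing = new_sp, origin = x$origin)
    }
  } else {
    if (order == 0L) storage.mode(out) <- "integer"
    out
  }
}

# Window resize used by the chunked path: evaluates the *global* resize
# mapping (identical arithmetic to the unchunked path, including rounding)
# for output planes offset by `out_off`, reading from a sub-array starting at
# 0-based plane `in_off` of the full input. Vectorised over the output block.
resize3d_window <- function(sub, out_dim, order, out_off, full_out, full_in,
                            in_off) {
  scale <- full_in / full_out
  gx <- (out_off[1] + seq_len(out_dim[1]) - 1 + 0.5) * scale[1] - 0.5
  gy <- (seq_len(out_dim[2]) - 1 + 0.5) * scale[2] - 0.5
  gz <- (seq_len(out_dim[3]) - 1 + 0.5) * scale[3] - 0.5
  clampi <- function(v, n) pmin(pmax(v, 0), n - 1)
  if (order == 0L) {
    i <- clampi(floor(gx + 0.5), full_in[1]) - in_off
    j <- clampi(floor(gy + 0.5), full_in[2])
    k <- clampi(floor(gz + 0.5), full_in[3])
    return(sub[i + 1, j + 1, k + 1, drop = FALSE])
  }
  fx <- pmin(pmax(gx, 0), full_in[1] - 1)
  fy <- pmin(pmax(gy, 0), full_in[2] - 1)
  fz <- pmin(pmax(gz, 0), full_in[3] - 1)
  x0 <- pmin(floor(fx), full_in[1] - 1); x1 <- pmin(x0 + 1, full_in[1] - 1)
  y0 <- pmin(floor(fy), full_in[2] - 1); y1 <- pmin(y0 + 1, full_in[2] - 1)
  z0 <- pmin(floor(fz), full_in[3] - 1); z1 <- pmin(z0 + 1, full_in[3] - 1)
  tx <- fx - x0; ty <- fy - y0; tz <- fz - z0
  acc <- array(0, out_dim)
  for (cc in 0:7) {
    xi <- (if (bitwAnd(cc, 1L)) x1 else x0) - in_off
    yi <- if (bitwAnd(cc, 2L)) y1 else y0
    zi <- if (bitwAnd(cc, 4L)) z1 else z0
    wx <- if (bitwAnd(cc, 1L)) tx else 1 - tx
    wy <- if (bitwAnd(cc, 2L)) ty else 1 - ty
    wz <- if (bitwAnd(cc, 4L)) tz else 1 - tz
    w <- outer(outer(wx, wy), wz)
    acc <- acc + w * sub[xi + 1, yi + 1, zi + 1, drop = FALSE]
  }
  acc
}
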