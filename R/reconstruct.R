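#' Lateral extension parameters
#'
#' @param start_fraction optional fraction along axis 1 overriding automatic
#'   detection of the extension start plane.
#' @param plane_threshold intensity threshold defining per-plane histology
#'   foreground (default 10).
#' @param min_object_px minimum connected foreground object size kept per
#'   plane (default 200).
#' @param erosion_base base erosion radius (voxels) for label tapering;
#'   atlas profiles override it per dataset.
#' @param taper_weighting scale each label's erosion radius by its normalised
#'   median depth inside the structure (centres taper first)?
#' @param label_dilation disk radius used to dilate the previous plane's
#'   labels when masking histology foreground (default 5).
#' @param direction `"down"` extends toward plane 1 (default), `"up"` toward
#'   the last plane; atlases differ in which hemisphere carries labels.
#' @return an `extension_params` list.
#' @export
extension_params <- function(start_fraction = NULL, plane_threshold = 10,
                             min_object_px = 200L, erosion_base = 3L,
                             taper_weighting = TRUE, label_dilation = 5L,
                             direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (!is.null(start_fraction)) {
    stopifnot(start_fraction >= 0, start_fraction < 1)
  }
  stopifnot(min_object_px >= 0, erosion_base >= 0)
  structure(list(start_fraction = start_fraction,
                 plane_threshold = plane_threshold,
                 min_object_px = as.integer(min_object_px),
                 erosion_base = as.integer(erosion_base),
                 taper_weighting = isTRUE(taper_weighting),
                 label_dilation = as.integer(label_dilation),
                 direction = direction),
            class = "extension_params")
}

#' Mirroring parameters
#'
#' @param mirror_fraction fraction along axis 1 at which planes are replaced
#'   by reflections (0 < fraction < 1).
#' @param rotations list of in-plane rotations applied before mirroring;
#'   each element `list(plane = "axial"|"coronal"|"sagittal" or axis number,
#'   degrees = ...)`.
#' @param negate_mirrored negate label IDs on the mirrored hemisphere?
#' @return a `mirror_params` list.
#' @export
mirror_params <- function(mirror_fraction = 0.5, rotations = list(),
                          negate_mirrored = FALSE) {
  stopifnot(mirror_fraction > 0, mirror_fraction < 1)
  structure(list(mirror_fraction = mirror_fraction, rotations = rotations,
                 negate_mirrored = isTRUE(negate_mirrored)),
            class = "mirror_params")
}

## ---- 2D helpers ------------------------------------------------------------

as3 <- function(m) array(m, c(dim(m), 1L))

components2d <- function(mask) {
  cc <- cpp_label_components(as3(mask), c(dim(mask), 1L))
  matrix(cc, dim(mask)[1], dim(mask)[2])
}

remove_small_objects2d <- function(mask, min_px) {
  if (min_px <= 0L || !any(mask)) return(mask)
  cc <- components2d(mask)
  sizes <- tabulate(cc[cc > 0L])
  keep <- which(sizes >= min_px)
  out <- matrix(cc %in% keep & mask, dim(mask)[1], dim(mask)[2])
  out
}

erode2d_ball <- function(mask, r) {
  if (r <= 0) return(mask)
  out <- mask_erode_ball(as3(mask), r)
  matrix(out, dim(mask)[1], dim(mask)[2])
}

dilate2d_ball <- function(mask, r) {
  if (r <= 0) return(mask)
  out <- mask_dilate_ball(as3(mask), r)
  matrix(out, dim(mask)[1], dim(mask)[2])
}

resize2d <- function(m, odim, order) {
  out <- cpp_resize3d(as.double(as3(m)), c(dim(m), 1L), c(odim, 1L), order)
  matrix(out, odim[1], odim[2])
}

bbox2d <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) return(NULL)
  t(apply(w, 2, range))
}

edt2d <- function(mask) {
  d <- sqrt(cpp_edt_sq(as3(mask), c(dim(mask), 1L), c(1, 1, 1)))
  matrix(d, dim(mask)[1], dim(mask)[2])
}

## ---- extension -------------------------------------------------------------

#' Find the lateral extension start plane
#'
#' Scans from the labeled-side edge of the stack inward and returns the most
#' lateral plane of the first contiguous run (>= `min_run` planes) of labeled
#' planes; isolated labeled planes are skipped. An `override` index, when
#' given, is returned verbatim (atlases whose lateral-most labeled planes are
#' incomplete specify the start manually).
#'
#' @param labels `label_volume` or integer array.
#' @param override optional plane index returned as-is.
#' @param direction `"down"`: labels occupy high plane indices and extension
#'   will proceed toward plane 1.
#' @param min_run minimum run length counting as contiguous (default 2).
#' @return 1-based plane index.
#' @export
find_extension_start <- function(labels, override = NULL,
                                 direction = c("down", "up"), min_run = 2L) {
  direction <- match.arg(direction)
  if (!is.null(override)) return(as.integer(override))
  lab <- vol_data(labels)
  n <- dim(lab)[1]
  has <- vapply(seq_len(n), function(p) any(lab[p, , ] != 0L), FALSE)
  if (!any(has)) stop("no labeled plane found")
  idx <- if (direction == "down") seq_len(n) else rev(seq_len(n))
  r <- rle(has[idx])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= min_run)
  pick <- if (length(cand)) starts[cand[1]] else starts[which(r$values)[1]]
  idx[pick]
}

#' Extend labels laterally, plane by plane
#'
#' Recursively annotates the unlabeled lateral planes: each new plane's
#' histology foreground (threshold, masked by the dilated previous labels,
#' small objects removed) is divided into connected structures; the previous
#' plane's labels are resized (order-0) per structure to the structure's
#' bounding box, in-painted against the foreground, eroded per label with a
#' radius scaled by the label's normalised median depth in the structure
#' (central labels taper first, and may vanish entirely), and regrown by a
#' compact watershed over the anatomical edge-distance landscape of that
#' plane. Every above-threshold voxel of a processed plane comes out
#' labeled; when every label of a plane tapers away, extension stops.
#'
#' @param vol intensity `volume`.
#' @param labels co-shaped `label_volume`; planes lateral to `start` are
#'   expected to be unlabeled.
#' @param start start plane (see [find_extension_start()]).
#' @param edge_map 3D anatomical edge map from [anatomical_edge_map()].
#' @param params [extension_params()].
#' @return `label_volume` (or array) with lateral planes annotated.
#' @export
extend_labels_lateral <- function(vol, labels, start, edge_map,
                                  params = extension_params()) {
  x <- vol_data(vol)
  lab <- vol_data(labels)
  stopifnot(identical(dim(x), dim(lab)), identical(dim(x), dim(edge_map)))
  n <- dim(lab)[1]
  if (!any(lab[start, , ] != 0L)) stop("start plane carries no labels")
  planes <- if (params$direction == "down") {
    if (start <= 1L) integer() else (start - 1L):1L
  } else {
    if (start >= n) integer() else (start + 1L):n
  }
  if (!length(planes)) return(labels)

  # negated in-plane distance landscape of the 3D edge map, sliced per plane
  edge_dist <- distance_transform(edge_map, spacing = c(1, 1, 1))
  out <- lab
  prev_p <- start

  for (p in planes) {
    prev_lab <- out[prev_p, , ]
    fg <- matrix(x[p, , ] > params$plane_threshold, dim(x)[2], dim(x)[3])
    fg <- fg & dilate2d_ball(prev_lab != 0L, params$label_dilation)
    fg <- remove_small_objects2d(fg, params$min_object_px)
    if (!any(fg)) { prev_p <- p; next }

    cc <- components2d(fg)
    new_plane <- matrix(0L, dim(fg)[1], dim(fg)[2])
    prev_fg <- prev_lab != 0L
    for (ci in seq_len(max(cc))) {
      comp <- cc == ci
      cb <- bbox2d(comp)
      # previous-plane labels overlapping this structure's bounding box
      pb_mask <- prev_fg
      pb_mask[-(cb[1, 1]:cb[1, 2]), ] <- FALSE
      pb_mask[, -(cb[2, 1]:cb[2, 2])] <- FALSE
      if (!any(pb_mask)) pb_mask <- prev_fg  # structure moved; use all labels
      pb <- bbox2d(pb_mask)
      tmpl <- prev_lab[pb[1, 1]:pb[1, 2], pb[2, 1]:pb[2, 2], drop = FALSE]
      fit <- resize2d(tmpl, c(cb[1, 2] - cb[1, 1] + 1L, cb[2, 2] - cb[2, 1] + 1L), 0L)
      sub <- new_plane[cb[1, 1]:cb[1, 2], cb[2, 1]:cb[2, 2], drop = FALSE]
      csub <- comp[cb[1, 1]:cb[1, 2], cb[2, 1]:cb[2, 2], drop = FALSE]
      sub[csub] <- as.integer(fit)[csub]
      new_plane[cb[1, 1]:cb[1, 2], cb[2, 1]:cb[2, 2]] <- sub
    }

    # fill above-threshold voxels missed by the resize
    gaps <- fg & (new_plane == 0L)
    if (any(gaps) && any(new_plane != 0L)) {
      new_plane <- matrix(cpp_inpaint(new_plane, as3(gaps), c(dim(fg), 1L),
                                      c(1, 1, 1)), dim(fg)[1], dim(fg)[2])
    }
    if (!any(new_plane != 0L)) { prev_p <- p; next }

    # taper-weighted erosion: central (deep) labels erode hardest
    depth <- edt2d(fg)
    max_d <- max(depth)
    seeds <- matrix(0L, dim(fg)[1], dim(fg)[2])
    for (id in setdiff(unique(as.vector(new_plane)), 0L)) {
      m <- new_plane == id
      r <- params$erosion_base
      if (params$taper_weighting && max_d > 0) {
        w <- stats::median(depth[m]) / max_d
        r <- round(params$erosion_base * w)
      }
      er <- erode2d_ball(m, r)
      seeds[er] <- id
    }
    if (!any(seeds != 0L)) break  # all labels tapered away: extension complete

    landsc <- -matrix(edge_dist[p, , ], dim(fg)[1], dim(fg)[2])
    ws <- cpp_compact_watershed(as.integer(as3(seeds)), as.double(as3(landsc)),
                                as3(fg), c(dim(fg), 1L), 0.005)
    ws <- matrix(ws, dim(fg)[1], dim(fg)[2])
    left <- fg & (ws == 0L)
    if (any(left)) {
      ws <- matrix(cpp_inpaint(ws, as3(left), c(dim(fg), 1L), c(1, 1, 1)),
                   dim(fg)[1], dim(fg)[2])
    }
    out[p, , ] <- ws
    prev_p <- p
  }
  with_data(labels, out)
}

#' Expand dorsoventrally compressed label planes
#'
#' For each plane in `planes`, resizes the labels from their own bounding box
#' to the bounding box of the largest connected histology foreground
#' component (order-0), correcting annotation planes that were stored
#' compressed relative to the microscopy.
#'
#' @param vol intensity `volume`.
#' @param labels co-shaped `label_volume`.
#' @param planes plane indices to fix.
#' @param plane_threshold foreground threshold (default 10).
#' @param min_object_px small-object removal size (default 200).
#' @return `label_volume` (or array) with those planes expanded.
#' @export
expand_compressed_planes <- function(vol, labels, planes, plane_threshold = 10,
                                     min_object_px = 200L) {
  x <- vol_data(vol)
  lab <- vol_data(labels)
  stopifnot(identical(dim(x), dim(lab)), all(planes >= 1),
            all(planes <= dim(x)[1]))
  out <- lab
  for (p in planes) {
    fg <- matrix(x[p, , ] > plane_threshold, dim(x)[2], dim(x)[3])
    fg <- remove_small_objects2d(fg, min_object_px)
    lp <- out[p, , ]
    if (!any(fg)) {
      warning("plane ", p, ": no histology foreground; left unchanged")
      next
    }
    if (!any(lp != 0L)) next
    cc <- components2d(fg)
    sizes <- tabulate(cc[cc > 0L])
    big <- cc == which.max(sizes)
    fb <- bbox2d(big)
    sb <- bbox2d(lp != 0L)
    tmpl <- lp[sb[1, 1]:sb[1, 2], sb[2, 1]:sb[2, 2], drop = FALSE]
    fit <- resize2d(tmpl, c(fb[1, 2] - fb[1, 1] + 1L, fb[2, 2] - fb[2, 1] + 1L), 0L)
    np <- matrix(0L, dim(lp)[1], dim(lp)[2])
    np[fb[1, 1]:fb[1, 2], fb[2, 1]:fb[2, 2]] <- as.integer(fit)
    out[p, , ] <- np
  }
  with_data(labels, out)
}

## ---- rotation / mirroring / shear / stripping ------------------------------

plane_axis <- function(plane) {
  if (is.numeric(plane)) return(as.integer(plane))
  switch(plane,
         sagittal = 1L,
         axial = 2L,
         coronal = 3L,
         stop("unknown plane: ", plane))
}

#' Rotate a stack in-plane until the midline is axis-parallel
#'
#' Applies each rotation as identical 2D rotations of every slice along the
#' named stacking axis (`"axial"` = axis 2, `"coronal"` = axis 3,
#' `"sagittal"` = axis 1). Intensities are interpolated bilinearly, labels
#' order-0; shape is preserved and exposed corners are background-filled.
#' Right angles map indices exactly.
#'
#' @param x `volume`, `label_volume`, or 3D array.
#' @param rotations list of `list(plane=, degrees=)`.
#' @param background fill value (default 0).
#' @return same type as `x`.
#' @export
rotate_to_midline <- function(x, rotations, background = 0) {
  dat <- vol_data(x)
  order <- if (is_label_volume(x) || is.integer(dat)) 0L else 1L
  cur <- as.double(dat)
  dim(cur) <- dim(dat)
  for (rot in rotations) {
    if (is.null(rot$degrees) || rot$degrees == 0) next
    ax <- plane_axis(rot$plane %||% rot$axis)
    cur <- cpp_rotate_stack(cur, dim(cur), ax, rot$degrees, order, background)
    dim(cur) <- dim(dat)
  }
  if (order == 0L) storage.mode(cur) <- "integer"
  with_data(x, cur)
}

#' Mirror intensity and labels across the sagittal midline
#'
#' Planes at 1-based index `> m`, where `m = round(fraction * N)`, are
#' replaced by reflections of the planes below: output plane `i` takes input
#' plane `2m - i + 1` (clamped at 1). Planes `1..m` are unchanged. With
#' `fraction = 0.5` and even `N` the result is exactly plane-symmetric.
#'
#' @param vol intensity `volume`.
#' @param labels co-shaped `label_volume`.
#' @param params a [mirror_params()] (or a bare fraction).
#' @return list with mirrored `vol` and `labels`.
#' @export
mirror_across_midline <- function(vol, labels, params = mirror_params(0.5)) {
  if (is.numeric(params)) params <- mirror_params(params)
  check_paired(vol, labels)
  xv <- vol_data(vol)
  xl <- vol_data(labels)
  n <- dim(xv)[1]
  m <- round(params$mirror_fraction * n)
  if (m >= 1L && m < n) {
    for (i in (m + 1L):n) {
      src <- max(1L, 2L * m - i + 1L)
      xv[i, , ] <- xv[src, , ]
      li <- xl[src, , ]
      if (params$negate_mirrored) li <- -li
      xl[i, , ] <- li
    }
  }
  list(vol = with_data(vol, xv), labels = with_data(labels, xl))
}

#' Piecewise 3D affine shear of a cuboid region
#'
#' Within `roi`, the planes along `shear_axis` are displaced along
#' `shift_axis` by a linear ramp from 0 to `max_shift` voxels. With
#' `attach_axis` set, the displacement additionally ramps line-by-line from 0
#' at the attachment face, so the sheared block stays connected to its
#' surroundings along two orthogonal faces. Displacements are integral
#' (order-0; labels are safe); vacated voxels are background-filled and
#' content shifted past the ROI edge is clipped.
#'
#' @param x `volume`, `label_volume`, or 3D array.
#' @param roi 3x2 matrix of 1-based inclusive bounds (rows = axes).
#' @param shear_axis axis (1-3) along which planes are indexed.
#' @param shift_axis axis along which content moves; defaults to the
#'   remaining axis when `attach_axis` is given.
#' @param attach_axis optional axis of the attachment face.
#' @param max_shift maximum displacement in voxels (may be negative).
#' @param background fill value.
#' @return same type as `x`.
#' @export
piecewise_affine_shear <- function(x, roi, shear_axis, shift_axis = NULL,
                                   attach_axis = NULL, max_shift,
                                   background = 0) {
  dat <- vol_data(x)
  d <- dim(dat)
  roi <- matrix(as.integer(roi), 3, 2)
  stopifnot(all(roi[, 1] >= 1), all(roi[, 2] <= d), all(roi[, 1] <= roi[, 2]))
  if (is.null(shift_axis)) {
    shift_axis <- setdiff(1:3, c(shear_axis, attach_axis))[1]
  }
  stopifnot(shear_axis != shift_axis,
            is.null(attach_axis) ||
              !(attach_axis %in% c(shear_axis, shift_axis)))
  extent <- roi[shift_axis, 2] - roi[shift_axis, 1] + 1L
  if (abs(max_shift) > extent) {
    stop("max_shift exceeds the ROI extent along the shift axis")
  }

  sub <- dat[roi[1, 1]:roi[1, 2], roi[2, 1]:roi[2, 2], roi[3, 1]:roi[3, 2],
             drop = FALSE]
  ds <- dim(sub)
  K <- ds[shear_axis]
  J <- if (!is.null(attach_axis)) ds[attach_axis] else 1L
  out <- array(background, ds)

  idx_template <- list(seq_len(ds[1]), seq_len(ds[2]), seq_len(ds[3]))
  for (k in seq_len(K)) {
    sk <- if (K > 1) max_shift * (k - 1) / (K - 1) else 0
    for (j in seq_len(J)) {
      sj <- if (!is.null(attach_axis) && J > 1) sk * (j - 1) / (J - 1) else sk
      shift <- as.integer(round(sj))
      src_idx <- idx_template
      src_idx[[shear_axis]] <- k
      if (!is.null(attach_axis)) src_idx[[attach_axis]] <- j
      line <- do.call(`[`, c(list(sub), src_idx, list(drop = FALSE)))
      ns <- ds[shift_axis]
      dst_idx <- src_idx
      if (shift == 0) {
        out <- do.call(`[<-`, c(list(out), dst_idx, list(line)))
      } else {
        valid_src <- if (shift > 0) seq_len(ns - shift) else (1 - shift):ns
        valid_dst <- valid_src + shift
        src2 <- src_idx
        src2[[shift_axis]] <- valid_src
        dst_idx[[shift_axis]] <- valid_dst
        seg <- do.call(`[`, c(list(sub), src2, list(drop = FALSE)))
        out <- do.call(`[<-`, c(list(out), dst_idx, list(seg)))
      }
    }
  }
  dat[roi[1, 1]:roi[1, 2], roi[2, 1]:roi[2, 2], roi[3, 1]:roi[3, 2]] <- out
  if (is_label_volume(x) || is.integer(vol_data(x))) storage.mode(dat) <- "integer"
  with_data(x, dat)
}

#' Strip non-CNS signal
#'
#' Crops both volumes to the labels' bounding box plus `pad` voxels (clamped
#' to the image) and zeroes intensity voxels outside the labels mask dilated
#' by a ball of radius `dilate` — removing embryo tissue and other signal
#' that carries no CNS annotation while keeping the labels' immediate
#' surroundings.
#'
#' @param vol intensity `volume`.
#' @param labels co-shaped `label_volume`, non-empty.
#' @param pad crop padding in voxels (default 5).
#' @param dilate ball radius for the retention mask (default 2).
#' @return list with cropped/stripped `vol` and `labels`.
#' @export
strip_non_cns <- function(vol, labels, pad = 5L, dilate = 2L) {
  check_paired(vol, labels)
  xv <- vol_data(vol)
  xl <- vol_data(labels)
  if (!any(xl != 0L)) stop("labels are empty; nothing to strip against")
  bb <- mask_bbox(xl != 0L)
  lo <- pmax(bb[, 1] - pad, 1L)
  hi <- pmin(bb[, 2] + pad, dim(xl))
  cv <- xv[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  cl <- xl[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  keep <- mask_dilate_ball(cl != 0L, dilate)
  cv[!keep] <- 0
  list(vol = with_data(vol, cv), labels = with_data(labels, cl))
}
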