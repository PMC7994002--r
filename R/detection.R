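#' Nuclei detection parameters
#'
#' Defaults follow a lightsheet nuclear-stain workflow: per-ROI percentile
#' clipping at the 5th/98.5th percentiles, saturation at the 50th percentile
#' of the rescaled signal, unsharp masking (sigma 8, amount 0.3), a light
#' octahedral erosion, then multi-scale Laplacian-of-Gaussian detection with
#' 10 scales, response threshold 0.1, and overlap-fraction pruning at 0.55.
#' The LoG scale range derives from the expected nucleus radius `r` through
#' the scale-space relation `sigma = r / sqrt(3)`, spanning 0.5x to 1.5x.
#'
#' @param nucleus_radius expected nucleus radius in voxels (sets the sigma
#'   range).
#' @param clip_low,clip_high percentile clip bounds (0-100).
#' @param saturation saturation percentile of the rescaled intensities.
#' @param unsharp_sigma,unsharp_amount unsharp-mask blur sigma (voxels) and
#'   detail amplification factor.
#' @param erosion_size octahedral (face-connected) erosion size; 0 disables.
#' @param n_sigma_steps number of LoG scales.
#' @param threshold minimum scale-normalised LoG response.
#' @param overlap_fraction blobs overlapping more than this are pruned to the
#'   stronger response.
#' @param chunk_shape chunk shape for whole-volume detection.
#' @param chunk_overlap chunk overlap in voxels (about a nucleus diameter).
#' @param preprocess run the percentile/unsharp preprocessing chain before
#'   detection (the dense-tissue regime it was calibrated for)? When FALSE,
#'   the raw ROI is min-max rescaled to `[0, 1]` so the response threshold
#'   keeps its meaning.
#' @param isotropic_interp resample axis 1 to near-isotropy before detection?
#' @param border_planes planes cropped per interior chunk face along axis 1
#'   (blob centres there are deferred to the neighbouring chunk).
#' @return a `detect_params` list.
#' @export
detect_params <- function(nucleus_radius = 5, clip_low = 5, clip_high = 98.5,
                          saturation = 50, unsharp_sigma = 8,
                          unsharp_amount = 0.3, erosion_size = 1L,
                          n_sigma_steps = 10L, threshold = 0.1,
                          overlap_fraction = 0.55,
                          chunk_shape = c(64L, 64L, 64L),
                          chunk_overlap = ceiling(2 * nucleus_radius),
                          preprocess = TRUE,
                          isotropic_interp = FALSE, border_planes = 1L) {
  stopifnot(clip_low >= 0, clip_low < clip_high, clip_high <= 100,
            threshold > 0, overlap_fraction >= 0, overlap_fraction <= 1,
            nucleus_radius > 0, n_sigma_steps >= 2)
  sigma0 <- nucleus_radius / sqrt(3)
  structure(list(nucleus_radius = nucleus_radius, clip_low = clip_low,
                 clip_high = clip_high, saturation = saturation,
                 unsharp_sigma = unsharp_sigma, unsharp_amount = unsharp_amount,
                 erosion_size = as.integer(erosion_size),
                 sigma_min = 0.5 * sigma0, sigma_max = 1.5 * sigma0,
                 n_sigma_steps = as.integer(n_sigma_steps),
                 threshold = threshold, overlap_fraction = overlap_fraction,
                 chunk_shape = as.integer(chunk_shape),
                 chunk_overlap = as.integer(chunk_overlap),
                 preprocess = isTRUE(preprocess),
                 isotropic_interp = isTRUE(isotropic_interp),
                 border_planes = as.integer(border_planes)),
            class = "detect_params")
}

empty_blobs <- function() {
  data.frame(plane = numeric(), row = numeric(), col = numeric(),
             radius = numeric(), response = numeric())
}

#' ROI preprocessing for nuclei detection
#'
#' Percentile clip, rescale to `[0, 1]`, saturate at the saturation
#' percentile, unsharp-mask, then a light greyscale erosion (octahedral
#' element) to separate touching blobs. Degenerate (constant) input comes
#' back as zeros without numeric faults; output is always within `[0, 1]`.
#'
#' @param roi `volume` or 3D array.
#' @param params [detect_params()].
#' @return numeric array in `[0, 1]`.
#' @export
preprocess_roi <- function(roi, params = detect_params()) {
  x <- as.double(vol_data(roi))
  d <- dim(vol_data(roi))
  dim(x) <- d
  qs <- stats::quantile(x, c(params$clip_low, params$clip_high) / 100,
                        names = FALSE, type = 7)
  if (qs[2] <= qs[1]) return(array(0, d))
  x <- pmin(pmax(x, qs[1]), qs[2])
  x <- (x - qs[1]) / (qs[2] - qs[1])
  s <- stats::quantile(x, params$saturation / 100, names = FALSE, type = 7)
  if (s > 0) {
    x <- pmin(x, s) / s
  }
  dim(x) <- d
  if (params$unsharp_amount > 0 && params$unsharp_sigma > 0) {
    blur <- cpp_gauss3d(x, d, rep(params$unsharp_sigma, 3), 4)
    x <- x + params$unsharp_amount * (x - blur)
    x <- pmin(pmax(x, 0), 1)
    dim(x) <- d
  }
  if (params$erosion_size > 0L) {
    for (i in seq_len(params$erosion_size)) {
      x <- cpp_minmax3(x, d, 6L, FALSE)
    }
    dim(x) <- d
  }
  x
}

#' Multi-scale LoG blob detection in an ROI
#'
#' Scale-normalised Laplacian-of-Gaussian responses are computed over
#' `n_sigma_steps` scales; local maxima of the 4D scale-space stack above
#' `threshold` become candidate blobs with radius `sigma * sqrt(3)`.
#' Overlapping detections beyond `overlap_fraction` are pruned, keeping the
#' stronger response. With `isotropic_interp`, axis 1 is linearly resampled
#' to near-isotropy first and centres mapped back. Blob centres are 1-based
#' voxel coordinates in the ROI frame (fractional only after merging).
#'
#' @param roi `volume` or 3D array.
#' @param spacing voxel spacing (um), used for the isotropy factor.
#' @param params [detect_params()].
#' @param preprocess run [preprocess_roi()] first?
#' @param drop_low,drop_high drop blobs centred in the first/last
#'   `border_planes` planes along axis 1?
#' @return data.frame of blobs: `plane`, `row`, `col`, `radius`, `response`.
#' @export
detect_blobs <- function(roi, spacing = c(1, 1, 1), params = detect_params(),
                         preprocess = params$preprocess, drop_low = FALSE,
                         drop_high = FALSE) {
  x <- if (preprocess) {
    preprocess_roi(roi, params)
  } else {
    # raw path: min-max rescale so the LoG threshold applies to unit range
    a <- as.double(vol_data(roi))
    rng <- range(a)
    if (rng[2] > rng[1]) a <- (a - rng[1]) / (rng[2] - rng[1])
    dim(a) <- dim(vol_data(roi))
    a
  }
  d <- dim(x)
  aniso <- spacing[1] / min(spacing)
  interp <- params$isotropic_interp && aniso > 1.05
  if (interp) {
    d_iso <- c(as.integer(round(d[1] * aniso)), d[2], d[3])
    x <- cpp_resize3d(x, d, d_iso, 1L)
    dim(x) <- d_iso
    dwork <- d_iso
  } else {
    dwork <- d
  }

  sigmas <- seq(params$sigma_min, params$sigma_max,
                length.out = params$n_sigma_steps)
  ns <- length(sigmas)
  stack <- numeric(prod(dwork) * ns)
  for (si in seq_len(ns)) {
    g <- cpp_gauss3d(x, dwork, rep(sigmas[si], 3), 4)
    lap <- cpp_laplace3(g, dwork)
    stack[((si - 1) * prod(dwork) + 1):(si * prod(dwork))] <-
      -sigmas[si]^2 * lap
  }
  peaks <- cpp_blob_peaks(stack, c(dwork, ns), params$threshold)
  if (nrow(peaks) == 0L) return(empty_blobs())

  blobs <- data.frame(
    plane = peaks[, 1] + 1,
    row = peaks[, 2] + 1,
    col = peaks[, 3] + 1,
    radius = sigmas[peaks[, 4] + 1] * sqrt(3),
    response = peaks[, 5]
  )
  if (interp) {
    # map interpolated plane coordinates back to the original grid
    scale1 <- d[1] / dwork[1]
    blobs$plane <- (blobs$plane - 1 + 0.5) * scale1 - 0.5 + 1
  }
  blobs <- prune_overlapping_blobs(blobs, params$overlap_fraction)
  if (drop_low) {
    blobs <- blobs[round(blobs$plane) > params$border_planes, , drop = FALSE]
  }
  if (drop_high) {
    blobs <- blobs[round(blobs$plane) <= d[1] - params$border_planes, ,
                   drop = FALSE]
  }
  rownames(blobs) <- NULL
  blobs
}

# Fraction of the smaller sphere's volume shared by two spheres.
sphere_overlap <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  rs <- min(r1, r2)
  rl <- max(r1, r2)
  if (d <= rl - rs) return(1)
  lens <- pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
  lens / (4 / 3 * pi * rs^3)
}

# Greedy strongest-first suppression of mutually overlapping blobs.
prune_overlapping_blobs <- function(blobs, overlap_fraction) {
  n <- nrow(blobs)
  if (n <= 1L) return(blobs)
  ord <- order(-blobs$response, blobs$plane, blobs$row, blobs$col)
  blobs <- blobs[ord, , drop = FALSE]
  keep <- rep(TRUE, n)
  for (i in seq_len(n - 1L)) {
    if (!keep[i]) next
    for (j in (i + 1L):n) {
      if (!keep[j]) next
      dd <- sqrt((blobs$plane[i] - blobs$plane[j])^2 +
                 (blobs$row[i] - blobs$row[j])^2 +
                 (blobs$col[i] - blobs$col[j])^2)
      if (dd < blobs$radius[i] + blobs$radius[j] &&
          sphere_overlap(dd, blobs$radius[i], blobs$radius[j]) >
            overlap_fraction) {
        keep[j] <- FALSE
      }
    }
  }
  out <- blobs[keep, , drop = FALSE]
  out[order(out$plane, out$row, out$col), , drop = FALSE]
}

#' Chunked whole-volume nuclei detection
#'
#' Splits the volume into overlapping chunks (overlap about a nucleus
#' diameter so border nuclei are seen whole by some chunk), detects per chunk
#' independently (results are chunk-order invariant), shifts coordinates to
#' the full-image frame, and prunes duplicates over the overlap grid along
#' each axis in turn.
#'
#' @param vol `volume` or 3D array.
#' @param params [detect_params()].
#' @param spacing spacing (um); taken from `vol` when it is a `volume`.
#' @return data.frame of blobs in full-image coordinates.
#' @export
detect_whole_volume <- function(vol, params = detect_params(), spacing = NULL) {
  x <- vol_data(vol)
  sp <- spacing %||% vol_spacing(vol)
  d <- dim(x)
  starts <- lapply(1:3, function(a) {
    chunk_starts(d[a], params$chunk_shape[min(a, length(params$chunk_shape))],
                 params$chunk_overlap)
  })
  grid <- expand.grid(i = seq_along(starts[[1]]), j = seq_along(starts[[2]]),
                      k = seq_along(starts[[3]]))
  all_blobs <- list()
  for (g in seq_len(nrow(grid))) {
    s <- c(starts[[1]][grid$i[g]], starts[[2]][grid$j[g]], starts[[3]][grid$k[g]])
    cs <- params$chunk_shape
    e <- pmin(s + cs - 1L, d)
    roi <- x[s[1]:e[1], s[2]:e[2], s[3]:e[3], drop = FALSE]
    b <- detect_blobs(roi, sp, params,
                      drop_low = s[1] > 1L, drop_high = e[1] < d[1])
    if (nrow(b)) {
      b$plane <- b$plane + s[1] - 1L
      b$row <- b$row + s[2] - 1L
      b$col <- b$col + s[3] - 1L
      all_blobs[[length(all_blobs) + 1L]] <- b
    }
  }
  if (!length(all_blobs)) return(empty_blobs())
  blobs <- do.call(rbind, all_blobs)
  blobs <- blobs[order(blobs$plane, blobs$row, blobs$col, blobs$radius), ,
                 drop = FALSE]
  rownames(blobs) <- NULL

  tol <- pmax(1, params$chunk_overlap / 2)
  for (a in 1:3) {
    regions <- overlap_regions(d, starts[[a]], params$chunk_shape, a,
                               params$chunk_overlap)
    if (length(regions)) blobs <- prune_duplicates(blobs, regions, rep(tol, 3))
  }
  blobs
}

chunk_starts <- function(n, chunk, overlap) {
  if (chunk >= n) return(1L)
  step <- max(1L, chunk - overlap)
  s <- seq(1L, n - 1L, by = step)
  s <- s[s + overlap <= n | s == 1L]
  # ensure full coverage
  if (s[length(s)] + chunk - 1L < n) s <- c(s, n - chunk + 1L)
  unique(pmin(s, n - chunk + 1L))
}

overlap_regions <- function(d, starts, chunk_shape, axis, overlap) {
  regs <- list()
  if (length(starts) < 2L) return(regs)
  for (t in 2:length(starts)) {
    lo <- starts[t]
    hi <- min(starts[t - 1L] + chunk_shape[min(axis, length(chunk_shape))] - 1L,
              d[axis])
    if (hi < lo) next
    box <- rbind(c(1L, d[1]), c(1L, d[2]), c(1L, d[3]))
    # expand by half the overlap so duplicate pairs straddling the slab
    # boundary (centres shifted by truncation at a chunk face) are compared
    pad <- ceiling(overlap / 2)
    box[axis, ] <- c(max(1L, lo - pad), min(d[axis], hi + pad))
    regs[[length(regs) + 1L]] <- box
  }
  regs
}

#' Merge duplicate blobs inside chunk-overlap regions
#'
#' Within each region, pairs of blobs whose coordinate-wise absolute
#' difference is within `tolerance` on every axis are replaced by a single
#' blob at their coordinate (and radius) mean, repeating until no pair
#' qualifies; blobs outside every region are untouched.
#'
#' @param blobs blob data.frame.
#' @param regions list of 3x2 boxes (1-based inclusive).
#' @param tolerance per-axis tolerance in voxels.
#' @return pruned blob data.frame.
#' @export
prune_duplicates <- function(blobs, regions, tolerance) {
  stopifnot(all(tolerance > 0))
  if (nrow(blobs) <= 1L) return(blobs)
  for (box in regions) {
    inside <- blobs$plane >= box[1, 1] & blobs$plane <= box[1, 2] &
      blobs$row >= box[2, 1] & blobs$row <= box[2, 2] &
      blobs$col >= box[3, 1] & blobs$col <= box[3, 2]
    idx <- which(inside)
    if (length(idx) < 2L) next
    sub <- blobs[idx, , drop = FALSE]
    repeat {
      merged <- FALSE
      n <- nrow(sub)
      if (n < 2L) break
      for (i in seq_len(n - 1L)) {
        hit <- 0L
        for (j in (i + 1L):n) {
          if (abs(sub$plane[i] - sub$plane[j]) <= tolerance[1] &&
              abs(sub$row[i] - sub$row[j]) <= tolerance[2] &&
              abs(sub$col[i] - sub$col[j]) <= tolerance[3]) {
            hit <- j
            break
          }
        }
        if (hit > 0L) {
          sub$plane[i] <- (sub$plane[i] + sub$plane[hit]) / 2
          sub$row[i] <- (sub$row[i] + sub$row[hit]) / 2
          sub$col[i] <- (sub$col[i] + sub$col[hit]) / 2
          sub$radius[i] <- (sub$radius[i] + sub$radius[hit]) / 2
          sub$response[i] <- max(sub$response[i], sub$response[hit])
          sub <- sub[-hit, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    blobs <- rbind(blobs[-idx, , drop = FALSE], sub)
    blobs <- blobs[order(blobs$plane, blobs$row, blobs$col, blobs$radius), ,
                   drop = FALSE]
    rownames(blobs) <- NULL
  }
  blobs
}

#' Evaluate detections against a truth set
#'
#' Optimal one-to-one matching (Hungarian assignment on isotropic-scaled
#' Euclidean distances, in micrometres) between detected and true nuclei.
#' Matching runs in two passes to avoid penalising border effects: first
#' within the inner sub-ROI (all coordinates at least `inner_margin` voxels
#' from the ROI faces), then remaining inner truths/detections against the
#' border shell. Pairs within `match_tol` um are true positives; unmatched
#' inner detections are false positives and unmatched inner truths false
#' negatives.
#'
#' @param detected,truth blob data.frames (`plane`, `row`, `col`).
#' @param match_tol matching tolerance in micrometres.
#' @param inner_margin margin (voxels) defining the inner sub-ROI.
#' @param spacing voxel spacing in micrometres.
#' @param roi_dim ROI shape (needed to place the inner sub-ROI).
#' @return list with `tp`, `fp`, `fn`, `recall`, `precision`, and `pairs`
#'   (matched pairs with distances).
#' @export
evaluate_detections <- function(detected, truth, match_tol = 5,
                                inner_margin = 2L, spacing = c(1, 1, 1),
                                roi_dim) {
  stopifnot(match_tol > 0)
  if (nrow(detected) == 0L && nrow(truth) == 0L) {
    return(list(tp = 0L, fp = 0L, fn = 0L, recall = 1, precision = 1,
                pairs = data.frame()))
  }
  um <- function(b) cbind(b$plane * spacing[1], b$row * spacing[2],
                          b$col * spacing[3])
  inner <- function(b) {
    b$plane >= 1 + inner_margin & b$plane <= roi_dim[1] - inner_margin &
      b$row >= 1 + inner_margin & b$row <= roi_dim[2] - inner_margin &
      b$col >= 1 + inner_margin & b$col <= roi_dim[3] - inner_margin
  }
  d_in <- which(inner(detected))
  t_in <- which(inner(truth))
  d_um <- um(detected)
  t_um <- um(truth)

  match_sets <- function(di, ti) {
    if (!length(di) || !length(ti)) {
      return(data.frame(det = integer(), tru = integer(), dist = numeric()))
    }
    cost <- outer(seq_along(di), seq_along(ti),
                  Vectorize(function(a, b) sqrt(sum((d_um[di[a], ] - t_um[ti[b], ])^2))))
    asg <- hungarian_assign(cost)
    ok <- which(!is.na(asg))
    dd <- vapply(ok, function(a) cost[a, asg[a]], 0)
    sel <- dd <= match_tol
    data.frame(det = di[ok[sel]], tru = ti[asg[ok[sel]]], dist = dd[sel])
  }

  p1 <- match_sets(d_in, t_in)
  rem_t <- setdiff(t_in, p1$tru)
  rem_d <- setdiff(d_in, p1$det)
  d_border <- setdiff(seq_len(nrow(detected)), d_in)
  t_border <- setdiff(seq_len(nrow(truth)), t_in)
  p2t <- match_sets(d_border, rem_t)   # inner truths rescued by border dets
  p2d <- match_sets(setdiff(rem_d, integer()), setdiff(t_border, p2t$tru))

  matched_truth <- length(unique(c(p1$tru, p2t$tru)))
  matched_det <- length(unique(c(p1$det, p2d$det)))
  fn <- length(t_in) - matched_truth
  fp <- length(d_in) - matched_det
  tp <- nrow(p1) + nrow(p2t)
  recall <- if (length(t_in)) matched_truth / length(t_in) else 1
  precision <- if (length(d_in)) matched_det / length(d_in) else 1
  list(tp = tp, fp = fp, fn = fn, recall = recall, precision = precision,
       pairs = rbind(p1, p2t, p2d))
}

# Optimal assignment wrapper: rows to columns, NA where a row is unassigned
# (only when nrow > ncol). Minimises total cost.
hungarian_assign <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  if (n <= m) {
    as.integer(cpp_hungarian(cost))
  } else {
    back <- cpp_hungarian(t(cost))  # assigns each column a row
    out <- rep(NA_integer_, n)
    out[back] <- seq_len(m)
    out
  }
}

#' Grid search over detection parameters
#'
#' Loops [detect_blobs()] + [evaluate_detections()] over a parameter grid and
#' returns the grid annotated with recall/precision, best first.
#'
#' @param roi `volume` or array.
#' @param truth truth blob data.frame.
#' @param grid named list of parameter vectors (any [detect_params()]
#'   arguments).
#' @param spacing voxel spacing (um).
#' @param match_tol matching tolerance (um).
#' @param inner_margin inner margin for evaluation (voxels).
#' @return data.frame, one row per combination, sorted by recall+precision.
#' @export
detection_grid_search <- function(roi, truth, grid, spacing = c(1, 1, 1),
                                  match_tol = 5, inner_margin = 2L) {
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(combos)), function(i) {
    args <- as.list(combos[i, , drop = FALSE])
    p <- do.call(detect_params, args)
    b <- detect_blobs(roi, spacing, p)
    ev <- evaluate_detections(b, truth, match_tol, inner_margin, spacing,
                              dim(vol_data(roi)))
    cbind(combos[i, , drop = FALSE],
          data.frame(n_detected = nrow(b), recall = ev$recall,
                     precision = ev$precision))
  })
  out <- do.call(rbind, res)
  out[order(-(out$recall + out$precision)), , drop = FALSE]
}

#' Blob CSV I/O
#'
#' Blob lists are stored as CSV with columns `plane,row,col,radius` (and
#' `response` when present).
#'
#' @param blobs blob data.frame.
#' @param path file path.
#' @return `read_blobs` returns a blob data.frame.
#' @export
write_blobs <- function(blobs, path) {
  utils::write.csv(blobs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blobs
#' @export
read_blobs <- function(path) {
  b <- utils::read.csv(path)
  stopifnot(all(c("plane", "row", "col") %in% names(b)))
  b
}
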