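#' Volumetric image containers
#'
#' A `volume` couples a 3D scalar array with per-axis physical voxel spacing
#' (micrometres) and an origin offset. A `label_volume` is a `volume` whose
#' data are integer region IDs (0 = background), optionally carrying a region
#' ontology table (`id`, `name`, `parent_id`, `level`).
#'
#' Axis order is `(plane, row, column)` with axis 1 the sagittal stacking
#' axis. Spacing must be strictly positive on every axis.
#'
#' @param data 3D numeric array (intensities) or integer-valued array (labels).
#' @param spacing numeric length-3, micrometres per voxel along each axis.
#' @param origin numeric length-3 physical offset in micrometres.
#' @param ontology optional `data.frame` with columns `id`, `name`, and
#'   optionally `parent_id`, `level`.
#' @return An object of class `volume` or `c("label_volume", "volume")`.
#' @examples
#' v <- volume(array(runif(27), c(3, 3, 3)), spacing = c(20, 1, 1))
#' l <- label_volume(array(0L, c(3, 3, 3)), spacing = c(20, 1, 1))
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_array3d(data)
  storage.mode(data) <- "double"
  check_spacing(spacing)
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "volume"
  )
}

#' @rdname volume
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         ontology = NULL) {
  data <- as_array3d(data)
  if (is.double(data) && any(data != round(data))) {
    stop("label data must be integer-valued")
  }
  storage.mode(data) <- "integer"
  check_spacing(spacing)
  if (!is.null(ontology)) {
    stopifnot(is.data.frame(ontology), all(c("id", "name") %in% names(ontology)))
  }
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin), ontology = ontology),
    class = c("label_volume", "volume")
  )
}

as_array3d <- function(data) {
  if (is.null(dim(data))) stop("data must be an array")
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  data
}

check_spacing <- function(spacing) {
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three strictly positive values (um/voxel)")
  }
  invisible(spacing)
}

#' @export
print.volume <- function(x, ...) {
  kind <- if (is_label_volume(x)) "label_volume" else "volume"
  cat(sprintf("<%s> %s voxels, spacing %s um\n", kind,
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x ")))
  if (is_label_volume(x)) {
    ids <- setdiff(unique(as.vector(x$data)), 0L)
    cat(sprintf("  %d labels%s\n", length(ids),
                if (!is.null(x$ontology)) " (with ontology)" else ""))
  } else {
    rng <- range(x$data)
    cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
  }
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

#' Test for label volumes
#' @param x object.
#' @return `TRUE` for `label_volume` objects.
#' @export
is_label_volume <- function(x) inherits(x, "label_volume")

#' Nonzero label IDs of a label volume
#' @param labels a `label_volume` (or integer array).
#' @return sorted integer vector of label IDs present (0 excluded).
#' @export
label_ids <- function(labels) {
  d <- if (is_label_volume(labels)) labels$data else labels
  sort(setdiff(unique(as.vector(d)), 0L))
}

# Internal: accept a volume/label_volume or bare array and return the array.
vol_data <- function(x) {
  if (inherits(x, "volume")) x$data else x
}

vol_spacing <- function(x, default = c(1, 1, 1)) {
  if (inherits(x, "volume")) x$spacing else default
}

# Internal: shared shape/spacing contract for paired inputs.
check_paired <- function(a, b) {
  if (!identical(dim(vol_data(a)), dim(vol_data(b)))) {
    stop("paired volumes must share their shape")
  }
  sa <- vol_spacing(a)
  sb <- vol_spacing(b)
  if (max(abs(sa - sb)) > 1e-8 * max(sa)) {
    stop("paired volumes must share their spacing")
  }
  invisible(TRUE)
}

# Internal: replace the data array, keeping metadata and class.
with_data <- function(x, data) {
  if (inherits(x, "volume")) {
    if (is_label_volume(x)) storage.mode(data) <- "integer"
    x$data <- data
    x
  } else {
    data
  }
}

#' Foreground thresholding
#'
#' Builds a boolean foreground mask from an intensity volume. `"mean"` uses
#' the mean intensity, `"otsu"` the Otsu histogram threshold, `"fixed"` a
#' caller-supplied value. The mask is TRUE where intensity strictly exceeds
#' the threshold.
#'
#' @param vol a `volume` or 3D array.
#' @param method one of `"mean"`, `"otsu"`, `"fixed"`.
#' @param value threshold for `method = "fixed"`.
#' @return logical array shaped like the input.
#' @examples
#' v <- array(c(0, 100), c(4, 4, 4))
#' mean(threshold_foreground(v, "mean"))  # half the voxels
#' @export
threshold_foreground <- function(vol, method = c("mean", "otsu", "fixed"),
                                 value = NULL) {
  method <- match.arg(method)
  x <- vol_data(vol)
  thr <- switch(method,
    mean = mean(x),
    fixed = {
      if (is.null(value)) stop("method = 'fixed' needs a threshold value")
      value
    },
    otsu = {
      rng <- range(x)
      if (rng[1] == rng[2]) {
        warning("constant image: Otsu threshold undefined, returning empty mask")
        return(array(FALSE, dim(x)))
      }
      # flatten to one frame: otsu() thresholds each frame of a 3D array
      EBImage::otsu(matrix(x, nrow = dim(x)[1] * dim(x)[2]),
                    range = rng, levels = 256L)
    }
  )
  mask <- x > thr
  dim(mask) <- dim(x)
  mask
}
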