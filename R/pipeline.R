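#' Atlas processing profile
#'
#' A named bundle of per-dataset parameters driving [run_atlas_pipeline()]:
#' which stages run and with what settings. Each atlas in a developmental
#' series typically needs its own profile (start plane, mirror fraction,
#' rotation angles, erosion radii); the package ships a profile table for the
#' eight developing-mouse-brain atlases it was designed around plus a
#' `synthetic` profile matched to the built-in phantom.
#'
#' @param name profile name.
#' @param extension [extension_params()] or `NULL` to skip lateral extension.
#' @param mirror [mirror_params()] or `NULL` to skip mirroring.
#' @param refine [refine_params()] or `NULL` to skip edge-aware refinement.
#' @param smooth [smooth_params()] used as the refine post-smoothing.
#' @param detect [detect_params()].
#' @param cluster [cluster_params()].
#' @param edge [edge_map_params()].
#' @param affines list of [piecewise_affine_shear()] argument lists, applied
#'   in order after rotation.
#' @param expand_planes plane indices for [expand_compressed_planes()], or
#'   `NULL`.
#' @param strip run [strip_non_cns()] after mirroring?
#' @return an `atlas_profile` list.
#' @export
atlas_profile <- function(name = "default", extension = extension_params(),
                          mirror = mirror_params(0.5), refine = refine_params(),
                          smooth = smooth_params("adaptive_opening"),
                          detect = detect_params(), cluster = cluster_params(),
                          edge = edge_map_params(), affines = list(),
                          expand_planes = NULL, strip = FALSE) {
  if (!is.null(refine)) refine$post_smooth <- smooth
  structure(list(name = name, extension = extension, mirror = mirror,
                 refine = refine, smooth = smooth, detect = detect,
                 cluster = cluster, edge = edge, affines = affines,
                 expand_planes = expand_planes, strip = isTRUE(strip)),
            class = "atlas_profile")
}

#' Shipped atlas profiles
#'
#' Reads the profile table installed with the package (a YAML file under
#' `extdata/`), covering the eight ADMBA-series atlases (rotation angles,
#' mirror fractions, and extension start fractions as printed for each
#' developmental stage) and the `synthetic` profile used with
#' [make_synthetic_atlas()].
#'
#' @param name profile name, e.g. `"E18.5"`, `"P56"`, `"synthetic"`.
#' @return an `atlas_profile`.
#' @export
load_profile <- function(name) {
  path <- system.file("extdata", "profiles.yaml", package = "volatlas")
  all <- yaml::read_yaml(path)
  if (!name %in% names(all)) {
    stop("unknown profile '", name, "'; available: ",
         paste(names(all), collapse = ", "))
  }
  profile_from_list(name, all[[name]])
}

#' @rdname load_profile
#' @param path YAML file holding one profile (top-level keys as in the
#'   shipped table).
#' @export
read_profile <- function(path) {
  y <- yaml::read_yaml(path)
  profile_from_list(y$name %||% tools::file_path_sans_ext(basename(path)), y)
}

profile_from_list <- function(name, y) {
  rot <- lapply(y$rotations, function(r) list(plane = r$plane, degrees = r$degrees))
  ext <- if (isTRUE(y$no_extension)) NULL else {
    do.call(extension_params, c(
      list(start_fraction = y$start_fraction),
      y$extension %||% list()
    ))
  }
  mir <- if (!is.null(y$mirror_fraction)) {
    mirror_params(y$mirror_fraction, rotations = rot)
  } else {
    NULL
  }
  refine <- do.call(refine_params, y$refine %||% list())
  smooth <- do.call(smooth_params, y$smooth %||% list())
  detect <- do.call(detect_params, y$detect %||% list())
  cluster <- do.call(cluster_params, y$cluster %||% list())
  edge <- do.call(edge_map_params, y$edge %||% list())
  atlas_profile(name = name, extension = ext, mirror = mir, refine = refine,
                smooth = smooth, detect = detect, cluster = cluster,
                edge = edge, affines = y$affines %||% list(),
                expand_planes = y$expand_planes, strip = isTRUE(y$strip))
}

#' Run the atlas reconstruction + refinement pipeline
#'
#' Stage order: optional compressed-plane expansion, lateral label extension,
#' in-plane rotations, optional piecewise affine shears, mirroring across the
#' midline, optional non-CNS stripping, edge-aware refinement (which ends in
#' adaptive smoothing). Per-stage intermediates can be kept; metric tables
#' (per-label Dice, edge distances, intensity CV, smoothing records) and a
#' provenance record are written when `out_dir` is given.
#'
#' @param vol intensity `volume` (or a file path).
#' @param labels `label_volume` (or a file path).
#' @param profile an [atlas_profile()].
#' @param out_dir optional output directory for volumes, CSVs, and
#'   provenance JSON.
#' @param keep_intermediates return per-stage label snapshots?
#' @return list with `vol`, `labels` (refined), `edge_map`, `report`, and
#'   optionally `stages`.
#' @export
run_atlas_pipeline <- function(vol, labels, profile = atlas_profile(),
                               out_dir = NULL, keep_intermediates = FALSE) {
  if (is.character(vol)) vol <- read_volume(vol)
  if (is.character(labels)) labels <- read_volume(labels, label = TRUE)
  check_paired(vol, labels)
  stages <- list()
  snap <- function(tag, lab) {
    if (keep_intermediates) stages[[tag]] <<- lab
  }

  if (!is.null(profile$expand_planes)) {
    labels <- expand_compressed_planes(vol, labels, profile$expand_planes)
    snap("expanded", labels)
  }
  if (!is.null(profile$extension)) {
    start <- if (!is.null(profile$extension$start_fraction)) {
      max(1L, round(profile$extension$start_fraction * dim(vol$data)[1]))
    } else {
      find_extension_start(labels, direction = profile$extension$direction)
    }
    edge <- anatomical_edge_map(vol, labels, profile$edge)
    labels <- extend_labels_lateral(vol, labels, start, edge, profile$extension)
    snap("extended", labels)
  }
  if (!is.null(profile$mirror) && length(profile$mirror$rotations)) {
    vol <- rotate_to_midline(vol, profile$mirror$rotations)
    labels <- rotate_to_midline(labels, profile$mirror$rotations)
    snap("rotated", labels)
  }
  for (af in profile$affines) {
    vol <- do.call(piecewise_affine_shear, c(list(vol), af))
    labels <- do.call(piecewise_affine_shear, c(list(labels), af))
  }
  if (!is.null(profile$mirror)) {
    mm <- mirror_across_midline(vol, labels, profile$mirror)
    vol <- mm$vol
    labels <- mm$labels
    snap("mirrored", labels)
  }
  if (profile$strip) {
    st <- strip_non_cns(vol, labels)
    vol <- st$vol
    labels <- st$labels
    snap("stripped", labels)
  }
  res <- if (!is.null(profile$refine)) {
    refine_atlas(vol, labels, profile$refine, profile$edge)
  } else {
    list(labels = labels, edge_map = NULL, report = NULL)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(res$labels, file.path(out_dir, "labels_refined.mhd"))
    if (!is.null(res$report)) {
      utils::write.csv(res$report$per_label,
                       file.path(out_dir, "label_dsc.csv"), row.names = FALSE)
      if (!is.null(res$report$smoothing_records)) {
        write_smoothing_records(res$report$smoothing_records,
                                file.path(out_dir, "smoothing_records.csv"))
      }
    }
    prov <- list(profile = profile$name, package = "volatlas",
                 version = as.character(utils::packageVersion("volatlas")),
                 timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out <- list(vol = vol, labels = res$labels, edge_map = res$edge_map,
              report = res$report)
  if (keep_intermediates) out$stages <- stages
  out
}

#' Run the whole-volume nuclei quantification pipeline
#'
#' Chunked detection, optional truth-set evaluation, heat-map construction,
#' per-label counts/volumes/densities (when a registered label volume is
#' supplied), and per-label DBSCAN cluster/noise quality.
#'
#' @param vol nuclear-stain `volume` (or path).
#' @param profile an [atlas_profile()] (its `detect`/`cluster` entries are
#'   used).
#' @param truth optional truth blob data.frame (or CSV path).
#' @param labels optional registered `label_volume` at the same shape as
#'   `vol` (or path).
#' @param out_dir optional output directory.
#' @return list with `blobs`, optional `evaluation`, `heatmap`,
#'   `label_stats`, `cluster_stats`.
#' @export
run_detection_pipeline <- function(vol, profile = atlas_profile(),
                                   truth = NULL, labels = NULL,
                                   out_dir = NULL) {
  if (is.character(vol)) vol <- read_volume(vol)
  if (is.character(truth)) truth <- read_blobs(truth)
  if (is.character(labels)) labels <- read_volume(labels, label = TRUE)
  sp <- vol_spacing(vol)
  blobs <- detect_whole_volume(vol, profile$detect, spacing = sp)
  out <- list(blobs = blobs)
  if (!is.null(truth)) {
    out$evaluation <- evaluate_detections(blobs, truth,
                                          match_tol = 2 * profile$detect$nucleus_radius * min(sp),
                                          inner_margin = 2L, spacing = sp,
                                          roi_dim = dim(vol_data(vol)))
  }
  if (!is.null(labels)) {
    out$heatmap <- nuclei_heatmap(blobs, scale = c(1, 1, 1),
                                  shape = dim(vol_data(labels)))
    out$label_stats <- per_label_stats(out$heatmap, labels, spacing = sp)
    out$cluster_stats <- cluster_label_nuclei(blobs, labels, spacing = sp,
                                              params = profile$cluster)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_blobs(blobs, file.path(out_dir, "blobs.csv"))
    if (!is.null(out$evaluation)) {
      ev <- out$evaluation
      jsonlite::write_json(ev[c("tp", "fp", "fn", "recall", "precision")],
                           file.path(out_dir, "evaluation.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    if (!is.null(out$label_stats)) {
      utils::write.csv(out$label_stats, file.path(out_dir, "label_stats.csv"),
                       row.names = FALSE)
      utils::write.csv(out$cluster_stats,
                       file.path(out_dir, "cluster_stats.csv"),
                       row.names = FALSE)
    }
  }
  out
}
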