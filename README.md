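# volatlas

Construction, refinement, and cellular quantification of 3D anatomical
atlases in R.

Developmental brain atlases are typically annotated plane by plane in 2D,
which leaves three kinds of damage in the assembled 3D volume: jagged label
borders in the orthogonal views, unannotated lateral sections and
hemispheres, and label borders that drift off the anatomical boundaries
visible in the histology. `volatlas` repairs all three and then measures
how well it did, both at voxel resolution and — via automated nuclei
detection — at cellular resolution.

The core operations:

* **Completion** — lateral label extension by recursive plane-wise
  template fitting (resize, in-paint, taper-weighted erosion, edge-guided
  regrowth), in-plane rotation to the midline, mirroring across a
  per-atlas sagittal fraction, piecewise 3D affine shears, non-CNS
  stripping.
* **Edge-aware refinement** — anatomical edge maps from
  Laplacian-of-Gaussian zero crossings; each label eroded to a core
  (rescued by its 3D skeleton) and regrown by a compact seeded watershed
  over the distance-to-edge landscape, so neighbouring labels meet on
  anatomical boundaries.
* **Adaptive smoothing** — morphological opening with a per-label radius
  (halved for labels ≤ 5000 voxels, closing fallback when a label would
  vanish), against a Gaussian baseline; scored by the compactness-based
  metric *smoothing quality* = compaction − displacement, where
  compactness = SA³/Vol² from a marching-tetrahedra surface mesh.
* **Nuclei quantification** — chunked whole-volume multi-scale LoG blob
  detection with overlap-grid duplicate pruning, Hungarian-assignment
  evaluation against truth sets (recall = TP/(TP+FN),
  precision = TP/(TP+FP)), per-label counts/volumes/densities, and
  DBSCAN cluster/noise statistics as a label-alignment score
  (eps in µm, min_samples = 2·ndim = 6).
* **Synthetic phantoms** — a jagged/partial atlas generator and a nuclei
  phantom with exact ground truth, so the whole pipeline is testable with
  no external data.

Volumes are read/written as MetaImage (`.mhd`/`.raw`), NIfTI
(`.nii`, `.nii.gz`), NRRD, and multi-page TIFF; tabular outputs are CSV;
per-atlas parameter profiles are YAML.

## Worked example

```r
library(volatlas)

# a degraded synthetic atlas: jagged labels, 10% unlabeled lateral planes,
# one hemisphere missing
fx <- make_synthetic_atlas(shape = c(64, 64, 64), jitter = 2,
                           unlabeled_fraction = 0.1, drop_hemisphere = TRUE,
                           seed = 19)
res <- run_atlas_pipeline(fx$vol, fx$degraded, load_profile("synthetic"))

# how far label borders sit from detected anatomical edges, before/after
res$report$edge_dist_before
#> [1] 22258.14
res$report$edge_dist_after
#> [1] 10491.39
```

The refinement moves the summed label-to-anatomical-edge distance down by
~53%, and the completed atlas agrees far better with the ground-truth
annotation than the degraded input did (mean per-label Dice 0.845 vs 0.573
on this fixture, whose degradation includes a missing hemisphere).

Detection on the clean nuclei phantom:

```r
ph <- make_synthetic_nuclei_volume(seed = 11)   # 128^3, 200 nuclei, SNR 5
p  <- detect_params(nucleus_radius = 5, preprocess = FALSE)
blobs <- detect_whole_volume(ph$vol$data, p)
ev <- evaluate_detections(blobs, ph$truth, match_tol = 5, inner_margin = 2,
                          spacing = c(1, 1, 1), roi_dim = c(128, 128, 128))
c(recall = ev$recall, precision = ev$precision)
#>    recall precision
#> 0.9950000 0.9851485
```

A thin command-line front end ships at `inst/scripts/volatlas`
(subcommands `synth-atlas`, `synth-nuclei`, `refine-atlas`, `smooth`,
`metrics`, `detect`, `density`, `run-all`).

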