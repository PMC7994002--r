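---
title: "Refining plane-wise 3D atlas annotations and quantifying nuclei with volatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining plane-wise 3D atlas annotations and quantifying nuclei with volatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volatlas)
```

## The problem

Volumetric reference atlases of the developing brain are usually assembled
from expert annotations drawn plane by plane in a single 2D orientation.
Three defect classes follow from that workflow: label borders that look
smooth in the drawing plane are jagged staircases in the two orthogonal
views; lateral sections (and often a whole hemisphere) were never annotated
at all; and label borders drift away from the anatomical boundaries visible
in the underlying histology. `volatlas` turns such partial, 2D-derived
annotations into complete, smooth, anatomically aligned 3D atlases, and
scores the result both at voxel resolution (overlap, compactness,
edge-distance metrics) and at cellular resolution (per-region nuclei counts,
densities, and clustering structure).

Throughout, a `volume` is a 3D intensity array with per-axis voxel spacing
in micrometres, axis order (plane, row, column) with axis 1 the sagittal
stacking axis, and a `label_volume` is a co-shaped integer array in which 0
is background and every nonzero value is a region ID.

## Completing a partial atlas

**Lateral extension.** The most lateral fully-annotated plane is located by
scanning inward for the first contiguous run of labeled planes (isolated
stray planes are skipped; atlases whose lateral planes are incompletely
annotated override the start explicitly). Annotation is then propagated
outward plane by plane: the histology foreground of the next plane
(intensity threshold, default 10, small objects under 200 px removed,
restricted to a disk-dilation of the previous plane's labels) is split into
connected structures; the previous labels are resized order-0 into each
structure's bounding box; unlabeled foreground is filled by nearest-label
in-painting; each label is eroded with a radius scaled by its normalised
median depth inside the structure, so central structures taper away first,
as they do anatomically; and the eroded labels regrow by a compact watershed
over the anatomical edge-distance landscape of that plane. Labels are
allowed to erode completely — that is how the lateral tapering of deep
structures is modelled.

**Rotation, mirroring, shears.** Many source volumes are slightly rotated
relative to their own mid-sagittal plane, so mirroring would duplicate or
truncate midline structures. Profiles therefore specify small in-plane
rotations (applied identically to every slice along the named axis;
bilinear for intensity, order-0 for labels) before the labeled hemisphere is
reflected across a per-atlas mirror fraction: output plane `i > m`
(`m = round(fraction * N)`) takes input plane `2m - i + 1`. A piecewise 3D
affine shear is available for structures that curve away from the midline:
within a cuboid ROI, planes along the shear axis shift by an integral linear
ramp, optionally ramping line-by-line from an attachment face so the sheared
block stays connected to its surroundings on two faces. Non-CNS signal is
stripped by cropping to the labels' bounding box (plus 5 voxels) and zeroing
intensity outside the labels mask dilated by a 2-voxel ball.

## Anatomical edge maps and edge-aware refinement

Gross anatomical boundaries are detected as the zero crossings of a
Laplacian-of-Gaussian response: a broad Gaussian blur (so only
structure-scale boundaries survive), a 3-point Laplacian, then a
morphological zero-crossing detector (a voxel is flagged where the
neighbourhood erosion and dilation of the signed response disagree in sign).
Responses outside the tissue foreground (Otsu threshold, optionally unioned
with the label mask to fill unlabeled holes such as ventricles) are
suppressed, and the outer surface of the foreground is added so the tissue
outline itself is always an edge. The blur sigma is expressed in voxels and
is a per-dataset profile parameter: it must sit below the scale of the
structures to be separated. The default of 5 voxels suits full-size atlas
volumes whose structures span tens to hundreds of voxels; the synthetic
phantom profile uses 2 voxels because its wedge-shaped regions are only
10-30 voxels across.

Refinement erodes each label to a trusted core and regrows it against the
edges. Seeds are the ball-erosion of each label (default radius 8; a
per-dataset choice) united with the 3D skeleton of a lightly eroded copy
(half the radius), which rescues thin sheets that a global erosion would
destroy; a label whose erosion and skeleton both vanish falls back to its
single deepest voxel, so every ID survives into the seeds.
Skeletonization here is the distance-transform ridge (26-neighbourhood
local maxima of the Euclidean distance transform) — a medial core that
serves the rescue role without the cost of topological thinning. Regrowth
is a compact seeded watershed over the negated spacing-aware Euclidean
distance transform of the edge map: voxels far from any anatomical edge sit
at basin bottoms and flood first, so fronts from neighbouring labels tend to
meet exactly on the edges; the compactness term (default 0.005) adds a
penalty proportional to the squared voxel distance from each flood's seed
origin, keeping basins from fingering along noisy landscapes. Flooding uses
face connectivity with a deterministic priority queue (elevation, then
insertion order), so refinement is bit-reproducible; mask voxels unreachable
from any seed (disconnected islands) are assigned their nearest label so
that the output is always an exact partition of the mask.

## Label smoothing and the smoothing quality metric

Two smoothers are provided. The *Gaussian baseline* reproduces the
historical approach: each label, largest to smallest, is extracted in its
padded bounding box as an ID-valued image, blurred (default sigma 0.5, two
passes), and voxels whose blurred value still rounds to the integer ID are
kept. Rounding to integer identities is the baseline's documented weakness:
labels with large fine-ontology IDs lose boundary voxels even at tiny
sigmas, sparse fragmented labels vanish outright, and expanded large labels
can overwrite small neighbours, which are simply gone when their turn
comes. The *adaptive morphological* smoother opens each label with a ball
structuring element (the `size` parameter is a radius, recorded as such in
the outputs), halving the radius for labels of at most 5000 voxels, and
switching to a closing — which contains the original and therefore cannot
erase it — whenever the opening would delete the label; no label is ever
lost. Both smoothers fill vacated voxels by nearest-label in-painting
(spacing-aware Euclidean metric; equidistant donors resolved to the lowest
linear index).

Smoothing quality is scored from 3D compactness `SA^3 / Vol^2` (minimised
by a sphere at `36*pi`): *compaction* is the fractional compactness drop,
*displacement* the fraction of the smoothed label outside its original
extent, *smoothing quality* their difference, and the atlas-wide value the
label-volume-weighted mean. Surface area comes from a marching-tetrahedra
mesh (iso-level 0.5, linear vertex interpolation, spacing-scaled vertices)
of the indicator field padded by one voxel and regularised by a 0.7-voxel
Gaussian. The regularisation matters: meshing a raw binary field
overestimates a sphere's area by about 9%, which cubes to a ~28% error in
compactness; at 0.7 voxels the digital-ball and digital-cube estimates sit
within 7% and 8% of their closed forms (`36*pi` and 216), the anchors the
test suite checks. Isolated single voxels blur below the iso-level, so any
label whose regularised field produces no surface is re-meshed from the raw
indicator rather than being reported with zero area.

## Nuclei detection and per-label statistics

Whole-volume detection splits the image into overlapping chunks (overlap
about one nucleus diameter), detects per chunk, maps coordinates to the
full-image frame, and merges duplicates inside the overlap grid slab by
slab along each axis (pairs within a per-axis tolerance, default half the
overlap, are replaced by their coordinate mean). Chunk results are
order-independent, so the procedure parallelises trivially and the chunked
count stays within a couple of percent of a single-pass detection.

The detector itself is multi-scale Laplacian-of-Gaussian: scale-normalised
responses (`sigma^2` times the Laplacian of the blurred image, negated so
bright blobs peak positively) over 10 scales spanning 0.5-1.5 times
`r / sqrt(3)` for an expected nucleus radius `r` voxels, 4D local maxima
above the response threshold (default 0.1 on unit-range input), and
overlap-fraction suppression (default 0.55) keeping the stronger of two
overlapping spheres. An optional preprocessing chain targets staining and
background variation in dense tissue: percentile clipping at the 5th/98.5th
percentiles, rescaling, saturation at the median of the rescaled signal,
unsharp masking (sigma 8, amount 0.3), and a light octahedral erosion. The
chain's percentile anchors assume the median voxel carries tissue-scale
signal, which holds in densely packed nuclear stains but not in sparse
phantoms; with preprocessing off, the raw ROI is min-max rescaled so the
threshold keeps its meaning. Evaluation against a truth set scales
coordinates to micrometres and finds an optimal one-to-one Hungarian
assignment, first inside an inner sub-ROI and then between remaining inner
objects and the border shell, so nuclei whose best match lies just outside
the ROI are not spuriously penalised; pairs within the match tolerance are
true positives, and recall and precision follow the standard definitions.

Per-region statistics rasterise blob centres into a heat map (scaled,
rounded, counted), sum counts within each label mask, convert label volumes
to mm^3 from the voxel spacing, and report density and the per-voxel count
CV. Label alignment is additionally scored by DBSCAN: centres are grouped
by the label at their rounded heat-map voxel (the same rule as counting, so
the two agree), clustered independently per label in micrometre coordinates
with `min_samples = 2 * ndim = 6` and a conservative `eps` of 20 um (the
k-distance elbow tool `knn_elbow_distances()`, k = 5, supports choosing
eps per dataset). Points that cannot be clustered are noise; a label
boundary cutting through the tissue's natural cell neighbourhoods strands
points on the wrong side, so total noise rises with misalignment and falls
as labels are refined toward the true boundary.

## The synthetic phantoms

`make_synthetic_atlas()` builds an ellipsoidal "brain" partitioned into a
solid core plus nested shells split into angular wedges — chunky,
mid-sagittally symmetric regions, chosen over random partitions because
every boundary is analytic and the layout is meaningful under mirroring and
lateral extension. Each region gets a distinct mean intensity (default ramp
100-220 over dark background, noise sd 5, so foreground thresholding and
edge detection behave as on stained tissue) and the degraded annotation
reproduces the plane-wise defect classes: independent per-plane
dilation/erosion of each region by up to the jitter amplitude (default 2
voxels — the jagged-edge artifact), a fraction of unlabeled lateral planes,
a droppable hemisphere, and an optional fragmented label of scattered
single voxels carrying a large integer ID (9999), the sparse-label class
the Gaussian baseline destroys. `make_synthetic_nuclei_volume()` places
Gaussian-profile blobs (profile sigma `radius / sqrt(2)`, so the
scale-space radius estimate returns the nominal radius) at rejection-sampled
centres with a minimum separation, over a uniform tissue background
(default 30) with additive noise set by the SNR (peak amplitude over noise
sd, default 5).

What the phantoms deliberately do not model: real histology texture and
staining gradients, partial-volume boundaries, anisotropic acquisition
artifacts, touching nuclei in the collision regime, and non-rigid
deformation between specimen and atlas. Passing tests therefore demonstrate
the correctness and internal consistency of the algorithms under known
ground truth, not end-to-end performance on any particular microscope's
data; on real data the per-dataset profile parameters (thresholds, erosion
radii, edge sigma, detection scales) carry the burden the phantoms cannot.

## Problem sizes and numerical choices

The standard fixtures are a 128-cubed jagged atlas (12 labels including the
fragmented one) for smoothing comparisons, a 96-cubed degraded atlas for
edge-aware refinement, and a 128-cubed phantom with 200 nuclei at SNR 5 for
detection — sizes at which every boundary effect of interest is several
voxels across while a full run of the suite stays comfortable on a laptop.
Other fixed choices, made once and documented here: the strict `>` in
foreground thresholding; ties in nearest-label in-painting resolved to the
lowest linear index; the reflection index map `2m - i + 1` with clamping at
plane 1; zero-crossing neighbourhoods are the face-connected ball of radius
1 (a `connectivity` argument exposes the full 3x3x3 box); label surfaces
use the cross-shaped element with array borders counting as background,
while the tissue outline uses border-as-foreground so volumes touching the
array edge do not sprout spurious surface; Gaussian kernels are truncated
at 4 sigma with symmetric boundary reflection (8 sigma for the edge-map
blur, where the cut-off ripple of a shorter kernel would register as ghost
zero crossings); the population standard
deviation is used in every CV; and two empty masks have Dice 1 by
convention.
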