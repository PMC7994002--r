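# Per-atlas processing profiles for the ADMBA developmental series.
# Rotations are in-plane degrees applied slice-wise along the named plane's
# stacking axis; mirror_fraction and start_fraction are fractions along the
# sagittal (plane) axis. Erosion radii are per-atlas, manually determined.

"E11.5":
  rotations:
    - {plane: axial, degrees: 5}
    - {plane: coronal, degrees: 1}
  mirror_fraction: 0.52
  no_extension: true
  strip: true
  edge: {background_strategy: threshold_only}

"E13.5":
  rotations:
    - {plane: axial, degrees: 4}
    - {plane: coronal, degrees: 2}
  mirror_fraction: 0.48
  strip: true

"E15.5":
  rotations:
    - {plane: axial, degrees: 4}
  mirror_fraction: 0.49
  strip: true

"E18.5":
  rotations:
    - {plane: axial, degrees: -1.5}
    - {plane: coronal, degrees: 2}
  mirror_fraction: 0.525
  start_fraction: 0.137
  expand_planes: [103, 104, 105, 106, 107]

"P4":
  rotations:
    - {plane: axial, degrees: -0.22}
  mirror_fraction: 0.487

"P14":
  rotations:
    - {plane: axial, degrees: 0.4}
  mirror_fraction: 0.50

"P28":
  rotations:
    - {plane: axial, degrees: -1}
  mirror_fraction: 0.48
  start_fraction: 0.11

"P56":
  mirror_fraction: 0.50
  start_fraction: 0.138

# Profile matched to make_synthetic_atlas(): phantom structures are a few
# times smaller than real atlas structures, so the edge-detection blur and
# the seed erosion scale down accordingly.
"synthetic":
  mirror_fraction: 0.5
  extension:
    erosion_base: 2
  edge:
    gaussian_sigma: 2
  refine:
    seed_erosion: 4
    skeleton_erosion: 2
  smooth:
    size: 2
  # the phantom is uniform; the percentile/unsharp chain targets staining
  # variation in dense tissue and is left off here
  detect:
    preprocess: no
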