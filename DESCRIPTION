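Package: volatlas
Title: Construction, Refinement, and Cellular Quantification of 3D Anatomical Atlases
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns partial, plane-wise 2D annotations of volumetric microscopy
    into complete, smooth, anatomically aligned 3D atlases, and scores atlas
    quality at voxel and nuclei resolution. Provides lateral label extension,
    midline rotation and mirroring, piecewise 3D affine shearing, anatomical
    edge maps (Laplacian-of-Gaussian zero crossings), edge-aware label
    refinement by compact seeded watershed, adaptive morphological label
    smoothing with a compactness-based smoothing quality metric, chunked
    multi-scale Laplacian-of-Gaussian nuclei detection with Hungarian-matching
    evaluation, and density/DBSCAN-based label quality scoring. Volumes are
    read and written in MetaImage, NIfTI, NRRD, and multi-page TIFF formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    oro.nifti
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
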