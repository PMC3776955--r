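Package: tonodepth
Title: Depth-Resolved Tonotopy Analysis for Auditory Midbrain fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Surface-based, depth-resolved analysis of tonotopic organization
    in small auditory structures imaged with high-resolution sparse-sampling
    fMRI, exercised end-to-end on a synthetic midbrain phantom. Builds a
    triangulated tissue surface with normals, curvature and vertex areas;
    computes nearest-vertex depth maps; summarises per-voxel frequency
    responses by their amplitude-weighted centroid and tuning width; makes
    virtual electrode-like penetrations normal to the surface and fits
    depth gradients of preferred frequency with bootstrap significance;
    and reports whole-structure area and gradient-direction summaries.
    Includes a synthetic phantom generator with a planted depth-wise
    frequency gradient for parameter-recovery validation, and a simulator
    of the adaptive two-up/one-down frequency-discrimination staircase task
    used during scanning.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    igraph,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
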