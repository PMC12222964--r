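Package: cssi3d
Title: Concave Nucleus Segmentation in 3D Refractive-Index Tomograms by
    Statistical Sub-Cube Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Label-free segmentation of concave (cup-like) cell nuclei in 3D
    refractive-index tomograms, as produced by holographic tomography of
    suspended cells. Implements the concave variant of Computational
    Segmentation based on Statistical Inference (CSSI): a low-RI initial
    guess, iterated two-sample similarity testing of voxel sub-cubes against
    a reference voxel group, outlier filtering, local pairwise convex linking
    that preserves surface concavities, and morphological closing. Ships a
    numerical cell-phantom generator with tunable nucleus concavity for
    validation, voxel-based 3D morphometry (dry-mass density, sphericity,
    convexity and concavity descriptors), segmentation scoring and
    population-discrimination statistics, and Fourier-coverage (optical
    transfer function) analysis of tomographic acquisition geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
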