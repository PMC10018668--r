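Package: isomargin
Title: Isocenter Placement Minimizing Nonuniform Setup Margins for
    Multi-Target Cranial Radiosurgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing the single treatment isocenter for multiple
    cranial targets treated with single-isocenter stereotactic radiosurgery.
    Implements a distance-dependent CTV-to-PTV margin model combining
    translational and rotational setup uncertainty, a voxelized margin-volume
    objective (the PTV minus CTV shell volume produced by nonuniform,
    per-boundary-point expansion), reference isocenters at the centers of
    geometry, volume, and surface, and two optimizers over isocenter position:
    exhaustive grid search and adaptive simulated annealing with reannealing.
    Includes phantom generators for sphere-target benchmark configurations,
    JSON case-file input/output, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
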