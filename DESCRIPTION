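Package: epiwound3d
Title: Three-Dimensional Hybrid Cell-Center/Vertex Simulation of Epithelial Wound Healing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the mechanics of flat epithelial monolayers with a
    three-dimensional hybrid cell-center/vertex model. Cells are prism-like
    polyhedra whose apical and basal boundary vertices are interpolated from
    Delaunay-triangulated cell centers; bar elements connecting nodes and
    vertices carry elastic and rest-length-remodelling (viscoelastic) forces,
    and a quadratic penalty keeps cell volumes near their reference values.
    The apical and basal surfaces re-triangulate independently after each
    converged step, so neighbour exchanges (T1 transitions) can differ between
    the two sides and are stitched through intermediate vertices. Includes a
    laser-ablation wound protocol with time-dependent apical purse-string and
    lateral contractility, observables (projected wound area, relative height,
    wound-edge counts, volume deviations), a synthetic hexagonal-patch
    generator, sensitivity and closure-threshold studies, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
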