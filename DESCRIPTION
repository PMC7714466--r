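Package: nucmorph
Title: 3D Nuclear Morphometry from Wide-Field Fluorescence Stacks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch extraction and quantification of individual cell nuclei
    from 3D wide-field fluorescence stacks. Provides an automatic 3D crop
    (autocrop) of every nucleus-sized object, two complementary single-nucleus
    segmentation methods (a sphericity-guided modified Otsu threshold and a
    slice-wise restricted gift-wrapping edge closure), a discrete-geometry
    (surfel) surface-area estimator alongside the classical exposed-face sum,
    per-nucleus shape descriptors (volume, surface area, flatness, elongation,
    sphericity), and watershed-based quantification of intranuclear domains
    (chromocenters, FISH signals) including distances to the nuclear envelope.
    A synthetic-image generator produces digitized spheres, bead fields and
    multi-nucleus ground-truth stacks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
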