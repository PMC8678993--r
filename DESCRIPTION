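Package: hippospec
Title: FT-IR Chemical Mapping and Seizure-Behavior Analysis of the
    Hippocampal Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies Fourier-transform infrared (FT-IR) hyperspectral
    maps of brain tissue sections: integrated band and massif absorbances
    with trapezoidal baseline correction, band-ratio chemical maps
    (including the amide I beta-sheet/alpha-helix ratio), per-layer
    region-of-interest statistics with border erosion and pixel-count
    quality control, Mann-Whitney group comparisons, and Ward hierarchical
    clustering of cumulative seizure-behavior features into severity
    subgroups.  Includes a synthetic-data module that generates layered
    tissue phantoms with known band composition and seizure logs with
    planted severity clusters, so the whole pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    data.table,
    jsonlite,
    EBImage,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
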