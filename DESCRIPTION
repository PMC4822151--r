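Package: cardiomorph
Title: Cardiomyocyte Volume, Nuclearity and Ploidy from Confocal Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Direct simultaneous measurement of cardiomyocyte volume, nuclearity
    (nuclei per cell) and ploidy (genome copies per nucleus) from two-channel
    (nuclear + membrane) confocal z-stacks of thick histological sections.
    Provides acquisition quality control on the nuclear-channel depth profile,
    3D nucleus segmentation with distance-transform watershed splitting,
    membrane-limited seeded-watershed cell segmentation with region merging for
    multinucleated cells, control-calibrated ploidy densitometry, per-animal and
    per-group summary statistics, and a repeatability assessment. A synthetic
    phantom generator produces membrane-delimited, nucleated rod-shaped cells
    with full ground truth so that every stage is testable without tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
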