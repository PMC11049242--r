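Package: gliaquant
Title: Microglia Morphometrics and Seizure-Readout Quantification for
    Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for studies of microglia and
    seizure activity in larval zebrafish. Provides 3D morphometrics of
    segmented microglia (volume, surface area, sphericity, process
    counts and lengths, ramification index, Sholl profiles), rule-based
    classification of activation state (branched, amoeboid,
    transitional), cell-body motility tracking, calcium dF/F0 transient
    detection, local field potential event detection, locomotor
    speed-bin scoring, group-comparison statistics, and synthetic-data
    generators with known ground truth for end-to-end validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    zoo,
    car,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
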