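Package: larvatrax
Title: Behavioral and Neural-Activity Phenotyping for Larval Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Zone-based locomotor metrics, thigmotaxis and phototaxis
    indices with a three-class light-preference classifier, visual-motor
    response phase analysis, seizure-like episode detection, slope-based
    calcium oscillation statistics, and a nonparametric statistical
    comparison harness for larval zebrafish assays.  Works from tracking
    CSV exports or from a bundled synthetic-data generator (correlated
    random walks in circular arenas, GCaMP-like fluorescence traces)
    so every analysis stage is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
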