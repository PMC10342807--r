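Package: sigreverse
Title: Transcriptional Signature Reversal Analysis for Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify whether a candidate compound drives gene
    expression in the opposite direction to a disease signature. Implements
    global treatment-effect detection on an expression study with a
    self-organising map and a permutation null, covariate-adjusted
    differential Z profiles with probe-to-gene collapsing, Stouffer
    composite Z meta-analysis across studies, a signed Kolmogorov-Smirnov
    type gene-set enrichment score calibrated against a resampling null,
    contingency-table concordance scoring with one-sided Fisher exact
    tests, and a stress-minimising radial embedding that places compounds
    around a disease target so that proximity encodes anti-correlation.
    Includes seeded synthetic-data generators that emulate the statistical
    structure of treated-versus-control brain expression studies, families
    of correlated disease profiles, pathway collections, and compound
    profile libraries, so that the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
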