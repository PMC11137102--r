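Package: cfcin
Title: Chromosomal-Instability Stratification of Metastatic Colorectal
    Cancer from Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for stratifying metastatic colorectal cancer
    patients into chromosomal-instability (CIN) clusters from low-coverage
    whole-genome sequencing of plasma cell-free DNA. Binned read counts are
    normalized against a healthy reference panel, segmented, and used to
    estimate tumor fraction; copy-number profiles are rescaled for tumor
    content before nearest-centroid CIN cluster assignment, and plasma
    calls are compared with matched tumor tissue. Companion modules score
    nucleosome-footprint deviation from fragment-start positions, compute
    region-level bisulfite methylation scores with tumor-content
    deconvolution, and relate cluster membership and on-treatment
    methylation dynamics to survival via Kaplan-Meier and multivariate Cox
    analyses. A fully synthetic paired tissue/plasma cohort generator with
    known ground truth makes every stage testable without access to
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
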