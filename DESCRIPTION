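Package: cnadose
Title: Integrated Copy-Number Aberration Calling and Dosage-Driven
    Expression Analysis for Two-Colour Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls DNA copy-number aberrations from array-CGH log-ratio
    profiles with an interval-score (ADM-style) detector, maps recurrent
    minimal common regions across a cohort, integrates copy number with
    gene-expression arrays to produce signed dosage fold changes (g1 vs
    g0 stratification), and implements the validation-cohort statistics
    used for candidate genes: 2^-ddCt relative quantification for qPCR,
    hybridization-control normalization for TRAC assays, and Mann-Whitney
    group comparisons with mean-based fold changes. Ships a synthetic
    cohort generator with planted ground truth so the whole pipeline is
    testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    limma,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
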