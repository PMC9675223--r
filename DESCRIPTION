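Package: seriamap
Title: Automatic Order-Robust Genetic Linkage Maps by Seriation and Bin Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic construction of statistically order-robust genetic
    linkage maps from biparental segregation data. A sparse scaffold map is
    built by seriation from seed marker pairs, densified into a framework map
    whose marker order is supported at a chosen LOD threshold, and all
    remaining polymorphic markers are then placed into framework bins to give
    a high-density total map. Supports BC, DH, F2, RIL, intermated RIL and
    outbred (CP) full-sib populations, with on-the-fly linkage-phase
    inference, EM-based multipoint estimation with missing-data imputation,
    genotyping-error detection, redundant-marker ("twin") handling, and a
    mapping-population simulator for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
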