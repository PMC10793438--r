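Package: mavenull
Title: Null-Model Calibration and Functional Classification for Pooled
    Variant Competition Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical machinery for saturation functional assays of
    missense variants read out by pooled growth competition (multiplexed
    assays of variant effect).  Simulates per-residue variant libraries,
    growth competition and sequencing; counts amino-acid variants from
    paired amplicon reads; calibrates a gamma generalized linear model
    null distribution on neutral-barcode control experiments; classifies
    variants as functionally deleterious, indeterminate or neutral from
    one-sided p-values combined across replicates with Fisher's method
    under Benjamini-Hochberg false-discovery-rate control; provides a
    normalized fold-change alternative classifier, in silico predictor
    benchmarking, and protein-domain enrichment analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
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
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
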