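Package: azotrace
Title: Multiplexed Nitrogen Isotope Tracing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed stable-isotope nitrogen tracing
    experiments in which a library of 15N-labelled nutrients is traced, in
    parallel medium stocks, into the nitrogen-containing metabolome. Converts
    long-format isotopologue peak tables (LC-MS samples or mass spectrometry
    imaging pixel grids) into natural-abundance-corrected fractional
    enrichments, applies probabilistic quotient normalization and a
    quality-filter cascade, computes differential labelling scores between two
    conditions, and assembles tracer-to-pathway Sankey flow sets. Includes a
    synthetic-data generator with known ground truth emulating a 30-tracer
    plasma-like-medium library traced into more than 100 nitrogenous
    metabolites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
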