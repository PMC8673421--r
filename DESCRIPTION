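Package: mutscreen
Title: Integrated Somatic Mutation Association and CRISPR Screen Analysis
    for Chemoresistance Gene Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Nominates chemoresistance genes by combining case-control
    somatic-mutation association statistics from whole-exome sequencing of
    treatment responders versus non-responders with gene-level
    positive-selection statistics from genome-wide CRISPR knockout drug
    screens. Provides per-gene and per-CNV-event odds ratios and Fisher
    exact tests, alpha-truncated robust rank aggregation with a permutation
    null for sgRNA count screens, set integration with provenance, and
    hypergeometric over-representation analysis against GMT annotation
    collections. A synthetic-data module generates cohorts, CNV-event
    matrices and negative-binomial screen counts with planted signal so
    every stage is verifiable against a known ground truth.
License: MIT
Encoding: UTF-8
Imports:
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
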