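Package: consensnet
Title: Consensome and High-Confidence-Target Network Analysis of
    Weight-Gain Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transcriptional regulatory network analysis of
    antipsychotic-induced weight gain (AIWG) phenotypes. Builds per-node
    ChIP-Seq consensomes from peak-strength records, calls high-confidence
    transcriptional targets (HCTs) at a percentile cutoff, and tests
    differential-expression gene sets against every node's HCT set with
    one-sided hypergeometric overlap statistics, sample odds ratios and
    Benjamini-Hochberg false discovery rate control. Includes cohort
    assignment of weight-gain prone and resistant animals, delta-delta-Ct
    relative expression, a Welch t screen with two-stage
    Benjamini-Krieger-Yekutieli adaptive FDR, cross-species ortholog
    mapping and conservation matrices, phenotype-node enrichment, and a
    synthetic regulatory-corpus generator with planted driver nodes for
    end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
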