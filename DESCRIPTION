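Package: aclandscape
Title: Always-Correlated Gene Co-Expression Landscape Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and comparison of "Always Correlated" (AC) gene
    co-expression landscapes from multi-condition expression data. Implements
    probe-to-gene preprocessing (dubious-probe removal, highest-expression
    probe collapse, detection-flag and variation filters), per-condition
    network inference with the PCIT (partial correlation and information
    theory) local-significance rule, edge intersection across condition
    networks, MCODE-style dense-module detection with a correlation cut-off
    sweep, flat hypergeometric gene-set enrichment, module-to-regulator
    transcription-factor ranking, and cross-platform landscape
    comparison under a confident 1:1 gene-identifier mapping. Includes a
    latent-factor synthetic-data generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
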