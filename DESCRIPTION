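Package: rcrnet
Title: Reverse Causal Reasoning on Signed Regulatory Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds signed two-layer causal network models of metastasis
    suppressor genes and their transcriptional regulators from curated
    statements in a Biological Expression Language (BEL) subset,
    contextualizes them against knockdown differential expression,
    scores drug perturbation profiles with an NPA-style (network
    perturbation amplitude) quadratic scorer, and prioritizes regulatory
    paths converging on a target node with concordance and coherence
    agreement statistics (Cohen's kappa, one-sided Kolmogorov-Smirnov D+).
    Includes calibrated synthetic-data generators with recorded ground
    truth and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
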