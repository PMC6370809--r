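Package: lysoflux
Title: Lysosomal/Autophagic Gene Expression Pipeline with Planted-Signal
    Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end transcriptomic analysis of lysosomal/autophagic
    gene regulation: two-group negative-binomial differential expression on
    counts with configurable fold-change/FDR gates, median-of-ratios
    normalization, gene-set intersection and composite z-score comparison,
    short-time-series model-profile clustering with permutation
    significance, hypergeometric (Fisher-exact) term enrichment,
    permutation-based gene set enrichment analysis, Pearson co-expression
    networks with k-core hub ranking, delta-delta-CT relative
    quantification, and seeded synthetic-data generators with truth tables
    for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
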