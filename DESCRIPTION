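Package: mitonet
Title: Seed-Anchored Mitotic Co-Expression Network Analysis and the MNAI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers a seed-anchored co-expression relevance network around
    the mitotic kinases PLK1, CENPE and AURKB with a permutation-derived
    correlation threshold, conserves it across expression cohorts, and scores
    samples with the mitotic network activity index (MNAI, the sum of the
    network genes' log2 expression). Downstream analyses cover tertile
    survival stratification (Kaplan-Meier, log-rank, Cox), a copy-number
    association scan of merged genomic regions against network-gene
    expression, Match-style position-weight-matrix promoter scanning for the
    amplified transcription factors, NCI-style dose-response processing
    (growth percent, GI50, TGI) with high- versus low-MNAI drug-sensitivity
    comparisons, and siRNA growth-screen statistics. A multi-layer synthetic
    cohort generator plants the assumed structure (amplicon-driven module
    expression, survival hazard, drug sensitivity, promoter motifs) so the
    whole pipeline is testable without external accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    igraph,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse,
    knitr
Config/testthat/edition: 3
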