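Package: crane
Title: Constrained Randomization of Weighted Networks and Disease-Module
    Significance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates ensembles of weighted bipartite (transcription
    factor by gene) and unipartite (co-expression) networks with exactly
    conserved node strengths and bounded edge weights (the CRANE
    algorithm), alongside three baseline generative nulls: a
    maximum-likelihood configuration model with exponential edge weights,
    a per-block normal stochastic block model, and stratified edge-weight
    permutation. These ensembles feed a differential-modularity pipeline
    that detects candidate disease modules by comparing a disease network
    against a matched control, scores every node, fits a normal null from
    the randomized ensemble, and reports per-node p-values,
    Benjamini-Hochberg adjusted significance and ranks. Includes
    bipartite (Barber-type) modularity community detection, consensus
    clustering over stochastic partitions, normalized mutual information,
    a planted-module simulation benchmark with Wilcoxon rank-sum and
    F-score evaluation, a hypergeometric gene-set enrichment threshold
    sweep over GMT collections, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    data.table,
    yaml,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
Config/testthat/edition: 3
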