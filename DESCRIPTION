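Package: metgrowth
Title: Horizontal and Vertical Growth of Metabolite-Centric Metabolic Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how gene duplication shaped a metabolic
    network. Reconstructs metabolite-centric directed multigraphs from
    BioCyc-style and KEGG-style pathway-database flat files, detects
    paralogous enzyme families by global sequence alignment, measures the
    effect of randomly collapsing paralogous families on the metabolic
    space, quantifies per-pair functional overlap with Dice coefficients
    over metabolite pairs and pathway memberships, locates divergent
    pairs by shortest-path distances, tests duplication-age enrichment
    with the hypergeometric distribution, and correlates paralog
    expression profiles. Ships a synthetic-study generator with planted
    ground truth so the whole pipeline is testable without any database
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    xml2,
    jsonlite,
    Rcpp,
    Biostrings,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
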