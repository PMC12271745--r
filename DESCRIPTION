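Package: chromanet
Title: Integrative Network Analysis of Chromatin Contacts and Gene Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls statistically significant intrachromosomal Hi-C contacts under a
    Fisher noncentral hypergeometric null with a monotone distance-decay spline,
    balances contact matrices by iterative correction (ICE), builds per-chromosome
    chromatin-interaction networks with gene-annotated, typed nodes, and quantifies
    rewiring between conditions (Jaccard indices, Z-weighted degree, neighbourhood
    dissimilarity with kneedle thresholding). Builds mutual-information co-expression
    networks by bootstrap consensus with a Poisson support test, integrates both into
    a two-layer network with gene-to-bin interlayer edges, detects Louvain communities,
    and quantifies community-membership change and coupled structure-expression change.
    Includes a synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    igraph,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
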