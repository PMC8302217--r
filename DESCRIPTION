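Package: intronless
Title: Comparative Genomics and Evolutionary Analysis of Intronless Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing intronless genes (IGs) with multi-exon genes
    (MEGs) across vertebrate genomes. Implements the gene-architecture
    classification cascade (single-exon, UTR-intron, curation filters),
    best-bidirectional-hit orthology graphs, cograph checking and editing,
    modular decomposition into event-labeled gene trees, species-tree
    reconciliation with duplication and loss inference, conservation-age
    assignment on a fixed seven-taxon ladder, CPM-based differential-expression
    classification (UP/DN/NC/NE), hypergeometric over-representation analysis
    with Benjamini-Hochberg correction, two-proportion z-tests for
    post-translational modification prevalence, a microprotein candidate
    screen, and locus-level synteny comparison. A simulator generates gene
    families by duplication and loss along the species tree together with
    annotations, similarity tables, count matrices and PTM tables with known
    ground truth, so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
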