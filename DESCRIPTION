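Package: coexnet
Title: Temporal Weighted Gene Coexpression Network Analysis with Paired
    Network Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds unsigned weighted gene coexpression networks from
    expression matrices (biweight midcorrelation, soft-threshold
    adjacency, topological overlap, module detection) and compares
    condition-paired networks by intramodular-connectivity rank change
    and permutation module-preservation Z statistics.  Includes
    SAM-style permutation differential expression with FDR estimation,
    module eigengene and gene/module-trait statistics, hypergeometric
    over-representation analysis against GMT gene-set collections,
    qPCR delta-delta-Ct quantification, and a synthetic-data generator
    that plants modules, connectivity perturbations and differential
    genes so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
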