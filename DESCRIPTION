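Package: devcoexpr
Title: Developmental Stage-Resolved Gene Co-Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of spatio-temporal gene co-expression in developmental
    expression atlases of the BrainSpan kind (donors x brain regions x genes,
    with donors grouped into developmental stages). Provides preprocessing
    (donor exclusion, nearest-neighbour imputation of missing regions,
    expression filtering, quantile normalization, log2 transform, stage
    assignment), stage-resolved gene-pair Spearman correlation trajectories,
    hierarchical clustering of trajectories into temporal co-expression
    modules, transcriptome-wide co-expression modules, hypergeometric gene-set
    over-representation with BH-FDR, a permutation null for the number of
    strongly co-expressed pairs in a gene list, within-module hub-gene degree
    ranking, and a seeded synthetic-atlas generator with planted co-expression
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
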