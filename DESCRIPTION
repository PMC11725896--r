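Package: seedatlas
Title: Spatial Transcriptome Atlas Analysis for Developing Seeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates laser-capture microdissection (LCM) bulk RNA-seq of
    dissected seed subregions with single-nucleus RNA-seq of whole seeds.
    Provides detection and prevalence summaries for subregion count data,
    negative-binomial exact tests for calling subregion- and regional-specific
    mRNAs, a from-scratch weighted gene coexpression core (soft thresholding,
    topological overlap, dynamic module detection, eigengenes) with spatial
    classification of modules, single-nucleus normalization, graph clustering
    and marker detection, hypergeometric assignment of cell clusters to seed
    subregions, gene-set enrichment, and a fully seeded synthetic seed
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    mclust,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
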