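Package: scHybrid
Title: Detection of Tumor-Immune Hybrid Cells in Droplet Single-Cell RNA-Seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies neoplastic-immune hybrid cells -- single cells
    co-expressing a tumor and an immune (macrophage/monocyte) lineage
    program -- in droplet single-cell RNA-seq data, and distinguishes them
    from artifactual sequencing doublets. Provides dual-lineage module
    scoring with binned expression-matched control genes, a cluster-level
    rank-test rule for calling hybrid clusters, three simulation-based
    doublet scores with a consensus cluster adjudication, hybrid-specific
    Wilcoxon differential expression with cross-sample panel selection and
    hypergeometric over-representation analysis, permutation-based
    ligand-receptor interaction inference, and threshold gating with
    percent-positive quantification for cyclic immunofluorescence
    intensity tables. A seeded synthetic-data generator with known
    hybrid/doublet ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    SingleCellExperiment
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    irlba,
    BiocNeighbors,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    mclust,
    uwot,
    jsonlite,
    knitr,
    rmarkdown
biocViews: SingleCell, Transcriptomics, Clustering, DifferentialExpression,
    GeneSetEnrichment, CellBiology
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
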