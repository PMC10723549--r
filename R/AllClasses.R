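#' HybridExperiment: container for a hybrid-cell analysis
#'
#' `HybridExperiment` extends [SingleCellExperiment::SingleCellExperiment]
#' and carries a droplet scRNA-seq count matrix together with everything the
#' hybrid-cell workflow accumulates: per-cell annotations (and, for synthetic
#' data, ground-truth labels) in `colData`, log-normalized expression as a
#' second assay, the PCA embedding in `reducedDims`, Leiden cluster labels,
#' dual-lineage module scores, the three doublet scores, and the cluster-level
#' hybrid calls / doublet adjudications in `metadata`.
#'
#' The validity method enforces the structural invariants the workflow relies
#' on: unique cell barcodes, unique gene symbols, and a non-negative `counts`
#' assay.
#'
#' @slot ... inherits all slots from `SingleCellExperiment`.
#'
#' @aliases HybridExperiment-class
#' @exportClass HybridExperiment
#' @importFrom methods setClass validObject new is as callNextMethod
#' @import SingleCellExperiment
setClass("HybridExperiment", contains = "SingleCellExperiment")

setValidity("HybridExperiment", function(object) {
    msg <- NULL
    if (is.null(colnames(object)))
        msg <- c(msg, "cell barcodes (colnames) must be set")
    else if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate cell barcodes")
    if (is.null(rownames(object)))
        msg <- c(msg, "gene symbols (rownames) must be set")
    else if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene symbols")
    if ("counts" %in% SummarizedExperiment::assayNames(object)) {
        cts <- SummarizedExperiment::assay(object, "counts")
        neg <- if (methods::is(cts, "CsparseMatrix"))
            length(cts@x) > 0L && min(cts@x) < 0 else any(cts < 0)
        if (neg)
            msg <- c(msg, "counts assay contains negative values")
    }
    if (is.null(msg)) TRUE else msg
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a HybridExperiment
#'
#' @param counts sparse (or dense) non-negative integer matrix, genes x cells,
#'   with gene symbols as rownames and cell barcodes as colnames.
#' @param colData per-cell annotation `data.frame` or `DataFrame` (one row per
#'   cell). Typically holds at least a `cell_type` column; synthetic data adds
#'   `population`, `mixture_lambda`, `parent_1`, `parent_2`.
#' @param sample_id scalar sample identifier stored in `colData$sample_id`
#'   when not already present.
#' @param ... further arguments passed to
#'   [SingleCellExperiment::SingleCellExperiment()].
#'
#' @return A [HybridExperiment-class] object.
#'
#' @examples
#' m <- Matrix::rsparsematrix(50, 20, density = 0.3,
#'                            rand.x = function(n) rpois(n, 2) + 1)
#' dimnames(m) <- list(paste0("G", 1:50), paste0("C", 1:20))
#' he <- HybridExperiment(m)
#' he
#'
#' @export
HybridExperiment <- function(counts, colData = NULL, sample_id = NULL, ...) {
    counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
    if (is.null(colData))
        colData <- S4Vectors::DataFrame(row.names = colnames(counts))
    else
        colData <- methods::as(colData, "DataFrame")
    if (!is.null(sample_id) && !"sample_id" %in% colnames(colData))
        colData$sample_id <- sample_id
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), colData = colData, ...)
    methods::new("HybridExperiment", sce)
}
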