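#' Read a 10x-style MTX triplet directory
#'
#' Loads `matrix.mtx` (genes as rows), `features.tsv` (gene symbols in the
#' first or second column) and `barcodes.tsv` from a directory, optionally
#' joined with a cell-annotation TSV (columns `barcode`, `cell_type`,
#' `sample_id`, ...).
#'
#' @param dir directory containing the triplet.
#' @param annotations optional path to an annotation TSV with header.
#' @param sample_id sample identifier used when the annotation has none.
#' @return a [HybridExperiment-class].
#' @export
readTenX <- function(dir, annotations = NULL, sample_id = basename(dir)) {
    mtx <- file.path(dir, "matrix.mtx")
    feat <- file.path(dir, "features.tsv")
    bar <- file.path(dir, "barcodes.tsv")
    for (f in c(mtx, feat, bar))
        if (!file.exists(f)) stop("missing file: ", f)
    m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    features <- utils::read.delim(feat, header = FALSE,
                                  stringsAsFactors = FALSE)
    symbols <- if (ncol(features) >= 2) features[[2]] else features[[1]]
    barcodes <- utils::read.delim(bar, header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(symbols) || ncol(m) != length(barcodes))
        stop("matrix dimensions do not match features/barcodes")
    dimnames(m) <- list(make.unique(symbols), barcodes)
    cd <- NULL
    if (!is.null(annotations)) {
        ann <- utils::read.delim(annotations, stringsAsFactors = FALSE)
        i <- match(barcodes, ann$barcode)
        if (anyNA(i)) stop("annotation missing for some barcodes")
        cd <- S4Vectors::DataFrame(ann[i, setdiff(colnames(ann), "barcode"),
                                       drop = FALSE],
                                   row.names = barcodes)
    }
    HybridExperiment(m, colData = cd, sample_id = sample_id)
}

#' Write a HybridExperiment as a 10x-style MTX triplet
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` and (when ground
#' truth is present) `annotations.tsv` with columns `barcode`,
#' `population`, `cell_type`, `sample_id`, `mixture_lambda`, `parent_1`,
#' `parent_2`.
#'
#' @param he a [HybridExperiment-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeTenX <- function(he, dir) {
    stopifnot(methods::is(he, "HybridExperiment"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(.counts(he), file.path(dir, "matrix.mtx"))
    utils::write.table(data.frame(rownames(he), rownames(he)),
                       file.path(dir, "features.tsv"),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines(colnames(he), file.path(dir, "barcodes.tsv"))
    cd <- SummarizedExperiment::colData(he)
    if ("population" %in% colnames(cd)) {
        keep <- intersect(c("population", "cell_type", "sample_id",
                            "mixture_lambda", "parent_1", "parent_2"),
                          colnames(cd))
        ann <- cbind(data.frame(barcode = colnames(he)),
                     as.data.frame(cd[, keep, drop = FALSE],
                                   row.names = NULL))
        utils::write.table(ann, file.path(dir, "annotations.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(dir)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line — name, description, then tab-separated
#' gene symbols.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
    fgsea::gmtPathways(path)
}
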