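.cd_col <- function(x, col) {
    cd <- SummarizedExperiment::colData(x)
    if (!col %in% colnames(cd)) return(NULL)
    out <- cd[[col]]
    names(out) <- colnames(x)
    out
}

#' @rdname HybridExperiment-accessors
#' @export
setMethod("clusterLabels", "HybridExperiment", function(x)
    .cd_col(x, "cluster"))

#' @rdname HybridExperiment-accessors
#' @export
setReplaceMethod("clusterLabels", "HybridExperiment", function(x, value) {
    stopifnot(length(value) == ncol(x))
    SummarizedExperiment::colData(x)$cluster <- factor(value)
    x
})

#' @rdname HybridExperiment-accessors
#' @export
setMethod("tumScore", "HybridExperiment", function(x) .cd_col(x, "tum_score"))

#' @rdname HybridExperiment-accessors
#' @export
setMethod("macScore", "HybridExperiment", function(x) .cd_col(x, "mac_score"))

#' @rdname HybridExperiment-accessors
#' @export
setMethod("doubletScores", "HybridExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    need <- c("pann", "knn_fraction", "density_ratio")
    if (!all(need %in% colnames(cd))) return(NULL)
    data.frame(barcode = colnames(x),
               pann = cd$pann,
               knn_fraction = cd$knn_fraction,
               density_ratio = cd$density_ratio,
               row.names = NULL)
})

#' @rdname HybridExperiment-accessors
#' @export
setMethod("hybridCalls", "HybridExperiment", function(x)
    S4Vectors::metadata(x)$hybrid_calls)

#' @rdname HybridExperiment-accessors
#' @export
setMethod("doubletAdjudication", "HybridExperiment", function(x)
    S4Vectors::metadata(x)$doublet_adjudication)

#' @rdname HybridExperiment-accessors
#' @export
setMethod("truthTable", "HybridExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (!"population" %in% colnames(cd))
        stop("no ground-truth 'population' column; ",
             "truth tables exist only for synthetic data")
    keep <- intersect(c("population", "sample_id", "mixture_lambda",
                        "parent_1", "parent_2"), colnames(cd))
    cbind(data.frame(barcode = colnames(x), row.names = NULL),
          as.data.frame(cd[, keep, drop = FALSE], row.names = NULL))
})

#' @importFrom methods show
setMethod("show", "HybridExperiment", function(object) {
    callNextMethod()
    cd <- SummarizedExperiment::colData(object)
    done <- c(
        if ("cluster" %in% colnames(cd))
            sprintf("clusters(%d)", nlevels(factor(cd$cluster))),
        if ("tum_score" %in% colnames(cd)) "lineage scores",
        if ("pann" %in% colnames(cd)) "doublet scores",
        if (!is.null(hybridCalls(object)))
            sprintf("hybrid calls(%d hybrid)",
                    sum(hybridCalls(object)$is_hybrid)))
    if (length(done))
        cat("workflow: ", paste(done, collapse = ", "), "\n", sep = "")
})
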