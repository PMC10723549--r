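#' @name HybridExperiment-accessors
#' @title Accessors for HybridExperiment results
#'
#' @description Convenience accessors for quantities the workflow writes into
#' a [HybridExperiment-class]: Leiden cluster labels, the two lineage module
#' scores, the per-cell doublet scores, the cluster-level hybrid calls and
#' doublet adjudications, and (for synthetic data) the ground-truth table.
#' Accessors return `NULL` (with the exception of `truthTable`, which errors)
#' when the corresponding step has not been run yet.
#'
#' @param x a `HybridExperiment`.
#' @param value replacement value (cluster labels: a factor or vector with one
#'   entry per cell).
#' @return `clusterLabels`: factor of per-cell cluster labels. `tumScore`,
#'   `macScore`: named numeric vectors. `doubletScores`: `data.frame` with
#'   columns `barcode`, `pann`, `knn_fraction`, `density_ratio`.
#'   `hybridCalls`, `doubletAdjudication`: the `data.frame`s produced by
#'   [callHybridClusters()] / [adjudicateClusters()]. `truthTable`: the
#'   synthetic ground-truth `data.frame`.
NULL

#' @rdname HybridExperiment-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname HybridExperiment-accessors
#' @export
setGeneric("clusterLabels<-",
           function(x, value) standardGeneric("clusterLabels<-"))

#' @rdname HybridExperiment-accessors
#' @export
setGeneric("tumScore", function(x) standardGeneric("tumScore"))

#' @rdname HybridExperiment-accessors
#' @export
setGeneric("macScore", function(x) standardGeneric("macScore"))

#' @rdname HybridExperiment-accessors
#' @export
setGeneric("doubletScores", function(x) standardGeneric("doubletScores"))

#' @rdname HybridExperiment-accessors
#' @export
setGeneric("hybridCalls", function(x) standardGeneric("hybridCalls"))

#' @rdname HybridExperiment-accessors
#' @export
setGeneric("doubletAdjudication",
           function(x) standardGeneric("doubletAdjudication"))

#' @rdname HybridExperiment-accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
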