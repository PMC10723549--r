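#' Run the full hybrid-cell identification workflow on one sample
#'
#' Chains the per-sample stages: gene QC filter, log-normalization, PCA
#' embedding with the cumulative/individual variance rule, Leiden
#' clustering, lineage marker ranking (top `n_top` genes up in tumor and in
#' macrophages), dual module scoring with binned controls, the three
#' simulation-based doublet scores with consensus cluster adjudication,
#' and finally cluster-level hybrid calling. Doublet adjudication runs
#' before calling so that flagged artifact clusters are excluded from the
#' calling comparison families and any call on a flagged cluster is
#' demoted.
#'
#' @param he a [HybridExperiment-class] with raw counts and a `cell_type`
#'   annotation column (tumor / macrophage at minimum).
#' @param min_cells gene filter (default 3).
#' @param n_top lineage markers per program (default 50).
#' @param nbin,n_ctrl module-score binning parameters (defaults 24 / 100).
#' @param resolution,k_neighbors Leiden clustering parameters. The
#'   pipeline default resolution is 3.0 — deliberately finer than the
#'   generic [clusterCells()] default — because a rare hybrid population
#'   (a few percent of cells) and adjacent heterotypic-doublet cells only
#'   separate into distinct clusters under over-clustering; the
#'   cluster-level doublet consensus needs that separation.
#' @param alpha hybrid-calling significance level (default 0.05).
#' @param rank_threshold doublet-consensus percentile threshold
#'   (default 0.8).
#' @param doublet_config a [doubletConfig()].
#' @param seed integer seed driving clustering, scoring and doublet
#'   simulation.
#' @param umap also compute UMAP coordinates (default FALSE).
#' @return the processed `HybridExperiment`; inspect [hybridCalls()],
#'   [doubletAdjudication()], [tumScore()], [macScore()],
#'   `metadata(x)$lineage_markers`.
#' @export
runHybridPipeline <- function(he, min_cells = 3, n_top = 50, nbin = 24,
                              n_ctrl = 100, resolution = 3.0,
                              k_neighbors = 20, alpha = 0.05,
                              rank_threshold = 0.8,
                              doublet_config = NULL, seed = 0,
                              umap = FALSE) {
    stopifnot(methods::is(he, "HybridExperiment"))
    he <- qcFilter(he, min_cells = min_cells)
    he <- logNormalize(he)
    he <- embedCells(he, seed = seed)
    he <- clusterCells(he, k_neighbors = k_neighbors,
                       resolution = resolution, seed = seed, umap = umap)
    mk <- rankLineageMarkers(he, "tumor", "macrophage", n_top = n_top)
    S4Vectors::metadata(he)$lineage_markers <-
        list(tumor = mk$markers_a, macrophage = mk$markers_b)
    he <- scoreLineages(he, mk$markers_a, mk$markers_b, nbin = nbin,
                        n_ctrl = n_ctrl, seed = seed)
    if (is.null(doublet_config)) doublet_config <- doubletConfig(seed = seed)
    he <- scoreDoublets(he, doublet_config)
    he <- adjudicateClusters(he, rank_threshold = rank_threshold)
    he <- callHybridClusters(he, alpha = alpha)
    he
}

#' Identify the cluster(s) called hybrid after adjudication
#'
#' @param he a processed [HybridExperiment-class].
#' @return character vector of cluster labels still called hybrid (may be
#'   empty).
#' @export
hybridClusterLabels <- function(he) {
    calls <- hybridCalls(he)
    if (is.null(calls)) stop("no hybrid calls; run callHybridClusters()")
    calls$cluster[calls$is_hybrid]
}
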