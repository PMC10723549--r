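#' Summarize module scores per cluster
#'
#' Per-cluster medians of the two lineage scores plus a majority-vote
#' lineage annotation (each cluster is annotated by the most frequent
#' per-cell `cell_type` among its members; lexicographically first label on
#' ties). This is the tabular counterpart of per-cluster score violin plots.
#'
#' @param he a [HybridExperiment-class] with cluster labels and lineage
#'   scores (see [clusterCells()], [scoreLineages()]).
#' @return `data.frame` with columns `cluster`, `lineage_annotation`,
#'   `median_tum_score`, `median_mac_score`, `n_cells`.
#' @export
summarizeClusters <- function(he) {
    stopifnot(methods::is(he, "HybridExperiment"))
    cl <- clusterLabels(he)
    ts <- tumScore(he); ms <- macScore(he)
    if (is.null(cl)) stop("no cluster labels; run clusterCells() first")
    if (is.null(ts) || is.null(ms))
        stop("missing module scores; run scoreLineages() first")
    if (anyNA(ts) || anyNA(ms)) stop("missing scores for clustered cells")
    ann <- SummarizedExperiment::colData(he)$cell_type
    if (is.null(ann)) stop("no 'cell_type' annotation")
    res <- lapply(levels(cl), function(k) {
        i <- which(cl == k)
        tab <- sort(table(ann[i]), decreasing = TRUE)
        data.frame(cluster = k,
                   lineage_annotation = names(tab)[1],
                   median_tum_score = stats::median(ts[i]),
                   median_mac_score = stats::median(ms[i]),
                   n_cells = length(i),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Call hybrid clusters by pairwise one-sided rank tests
#'
#' A cluster is called hybrid when it sits above *both* lineages at once:
#' its tumor score is stochastically greater than that of every non-tumor
#' (immune/stromal) cluster, and its macrophage/monocyte score is
#' stochastically greater than that of every tumor-annotated cluster. Each
#' comparison is a one-sided Mann-Whitney (Wilcoxon rank-sum) test on the
#' per-cell scores; p-values are Benjamini-Hochberg adjusted within each
#' comparison family, and the call requires every adjusted p <= `alpha`
#' *and* a common-language effect size (AUC, the probability that a random
#' candidate cell outscores a random reference cell) of at least `min_auc`
#' in every comparison. The effect-size floor encodes that a hybrid
#' cluster's elevation must be visible at the per-cell level — the
#' violin-plot criterion — and keeps technically confounded but
#' practically negligible shifts (e.g. a low-depth pure-tumor subcluster
#' whose scores compress toward zero) from being called on significance
#' alone. Zero, one or several clusters may be called.
#'
#' The decision is rank-based, hence invariant to monotone transformations
#' of the scores and to cluster relabeling.
#'
#' Two kinds of cluster are excluded from the comparison families because
#' they are not valid lineage references: clusters already flagged as
#' doublet artifacts (see [adjudicateClusters()]) — any call on such a
#' cluster is demoted immediately — and clusters that are themselves
#' extreme outliers on the opposite-lineage score (Tukey boxplot rule,
#' median above Q3 + 1.5 IQR of the cluster medians within the family).
#' The latter keeps several hybrid clusters in one sample, or residual
#' unflagged artifact clusterettes, from blocking each other's calls; a
#' sample may legitimately contain more than one hybrid cluster. Running
#' the doublet consensus before calling gives the fully adjudicated
#' workflow; calling first and adjudicating afterwards demotes the same
#' calls but compares against artifact clusters.
#'
#' @param he a [HybridExperiment-class] with clusters and lineage scores.
#' @param alpha significance level for the adjusted p-values (default 0.05).
#' @param min_auc per-comparison effect-size floor (default 0.75).
#' @param exclude_clusters clusters excluded from the comparison families
#'   (default: clusters flagged by a previously run
#'   [adjudicateClusters()], if any).
#' @return the input, with the call table stored in
#'   `metadata(x)$hybrid_calls` (also retrievable via [hybridCalls()]):
#'   columns `cluster`, `lineage_annotation`, `n_cells`, `max_adj_p_tum`,
#'   `max_adj_p_mac`, `is_hybrid`, `demoted`, `reason`. Per-comparison
#'   details are kept in `metadata(x)$hybrid_call_detail`.
#' @export
callHybridClusters <- function(he, alpha = 0.05, min_auc = 0.75,
                               exclude_clusters = NULL) {
    stopifnot(methods::is(he, "HybridExperiment"))
    .assert_scalar_num(alpha, "alpha", 0, 1)
    summ <- summarizeClusters(he)
    cl <- clusterLabels(he)
    ts <- tumScore(he); ms <- macScore(he)
    adj <- doubletAdjudication(he)
    if (is.null(exclude_clusters) && !is.null(adj))
        exclude_clusters <- adj$cluster[adj$flagged_doublet]
    ref <- setdiff(summ$cluster, exclude_clusters)
    tumor_cl <- intersect(ref,
                          summ$cluster[summ$lineage_annotation == "tumor"])
    nontum_cl <- setdiff(ref, tumor_cl)
    # clusters that are themselves outliers on the opposite-lineage score
    # (Tukey boxplot rule on cluster medians) are other hybrid candidates or
    # residual artifacts, not valid lineage references: several hybrid
    # clusters in one sample must not block each other's calls
    outlier_high <- function(cls, med) {
        v <- med[match(cls, summ$cluster)]
        q <- stats::quantile(v, c(0.25, 0.75))
        cls[v > q[2] + 1.5 * (q[2] - q[1])]
    }
    mac_outlier <- outlier_high(tumor_cl, summ$median_mac_score)
    tum_outlier <- outlier_high(nontum_cl, summ$median_tum_score)
    if (length(tumor_cl) == 0)
        stop("no tumor-annotated cluster; hybrid calling needs at least ",
             "one tumor and one immune/stromal cluster")
    if (length(nontum_cl) == 0)
        stop("no immune/stromal cluster; hybrid calling needs at least ",
             "one tumor and one immune/stromal cluster")

    one_sided <- function(score, h, others) {
        if (length(others) == 0) return(NULL)
        x <- score[cl == h]
        cmp <- vapply(others, function(c2) {
            y <- score[cl == c2]
            p <- suppressWarnings(stats::wilcox.test(
                x, y, alternative = "greater")$p.value)
            r <- rank(c(x, y))
            w <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
            c(p = p, auc = w / (length(x) * length(y)))
        }, numeric(2))
        data.frame(vs_cluster = others, one_sided_p = cmp["p", ],
                   adjusted_p = stats::p.adjust(cmp["p", ], method = "BH"),
                   auc = cmp["auc", ],
                   stringsAsFactors = FALSE)
    }

    detail <- list()
    calls <- summ
    calls$max_adj_p_tum <- NA_real_
    calls$max_adj_p_mac <- NA_real_
    calls$is_hybrid <- FALSE
    for (i in seq_len(nrow(summ))) {
        h <- summ$cluster[i]
        tum_cmp <- one_sided(ts, h, setdiff(nontum_cl, c(h, tum_outlier)))
        mac_cmp <- one_sided(ms, h, setdiff(tumor_cl, c(h, mac_outlier)))
        detail[[h]] <- list(tum_comparisons = tum_cmp,
                            mac_comparisons = mac_cmp)
        ok_tum <- !is.null(tum_cmp) && all(tum_cmp$adjusted_p <= alpha) &&
            all(tum_cmp$auc >= min_auc)
        ok_mac <- !is.null(mac_cmp) && all(mac_cmp$adjusted_p <= alpha) &&
            all(mac_cmp$auc >= min_auc)
        calls$max_adj_p_tum[i] <- if (is.null(tum_cmp)) NA_real_ else
            max(tum_cmp$adjusted_p)
        calls$max_adj_p_mac[i] <- if (is.null(mac_cmp)) NA_real_ else
            max(mac_cmp$adjusted_p)
        calls$is_hybrid[i] <- ok_tum && ok_mac
    }
    # candidate-level control: the call for one cluster is an
    # intersection-union test (every comparison must be significant), whose
    # p-value is the largest adjusted comparison p; with tens of candidate
    # clusters tested, these are BH-adjusted across clusters so that
    # noise-level elevation in a pure-lineage cluster cannot sneak through
    calls$candidate_p <- pmax(calls$max_adj_p_tum, calls$max_adj_p_mac)
    calls$candidate_p_adj <- NA_real_
    has_p <- !is.na(calls$candidate_p)
    calls$candidate_p_adj[has_p] <- stats::p.adjust(calls$candidate_p[has_p],
                                                    method = "BH")
    calls$is_hybrid <- calls$is_hybrid & !is.na(calls$candidate_p_adj) &
        calls$candidate_p_adj <= alpha
    calls$demoted <- FALSE
    calls$reason <- NA_character_
    calls$alpha <- alpha
    demote <- calls$is_hybrid & calls$cluster %in% exclude_clusters
    if (any(demote)) {
        calls$is_hybrid[demote] <- FALSE
        calls$demoted[demote] <- TRUE
        calls$reason[demote] <-
            "doublet consensus: percentile rank above threshold in >= 2 methods"
    }
    S4Vectors::metadata(he)$hybrid_calls <- calls
    S4Vectors::metadata(he)$hybrid_call_detail <- detail
    he
}
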