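#' Differential expression between two cell sets
#'
#' Per-gene two-sided Wilcoxon rank-sum test on the log-normalized matrix
#' with Bonferroni adjustment, Seurat-convention log2 fold changes and
#' expression fractions. Typical use: an identified hybrid cluster versus
#' the annotated tumor cells, and versus the annotated macrophages, with
#' hybrid-cluster cells removed from the reference side beforehand.
#'
#' @param he a [HybridExperiment-class] with `logcounts`.
#' @param cells_a,cells_b disjoint cell selections (barcodes, indices or
#'   logical vectors), each of at least 3 cells.
#' @return `data.frame` with `gene`, `log2fc` (a vs b), `p_value`,
#'   `p_adjusted`, `pct_a`, `pct_b`.
#' @export
differentialExpression <- function(he, cells_a, cells_b) {
    stopifnot(methods::is(he, "HybridExperiment"))
    idx <- function(x) {
        if (is.character(x)) match(x, colnames(he))
        else if (is.logical(x)) which(x)
        else as.integer(x)
    }
    a <- idx(cells_a); b <- idx(cells_b)
    if (anyNA(a) || anyNA(b)) stop("unknown cell barcodes")
    if (length(intersect(a, b)) > 0) stop("cell sets overlap")
    if (length(a) < 3 || length(b) < 3)
        stop("each group needs at least 3 cells")
    .wilcox_de(.logcounts(he), a, b)
}

# per-sample significance filter used by the panel-selection rule
.passes <- function(de, alpha, lfc, direction) {
    sig <- de$p_adjusted <= alpha
    if (direction == "up") de$gene[sig & de$log2fc >= lfc]
    else de$gene[sig & de$log2fc <= -lfc]
}

#' Select the cross-sample shared gene panel
#'
#' Applies the visualization-panel selection rules to per-sample DE tables
#' of the hybrid-vs-tumor and hybrid-vs-macrophage comparisons:
#' per sample, keep genes with adjusted p <= `alpha_adj` and |log2FC| >=
#' `lfc_gene`; keep genes passing in at least `min_samples_shared` samples;
#' then narrow the two overcrowded categories — hybrid-vs-tumor
#' *upregulated* genes are ranked by (minimum) adjusted p and cut to
#' `top_k_up_vs_tumor`, and hybrid-vs-macrophage *downregulated* genes are
#' kept only with log2FC <= `lfc_floor_down_vs_mac` (in every passing
#' sample). The union of the four categories is returned with provenance.
#' An explicit `include` list supports manually curated additions.
#'
#' @param per_sample named list; each element is a list with `vs_tumor` and
#'   `vs_mac` DE tables from [differentialExpression()].
#' @param alpha_adj adjusted-p threshold (default 0.05).
#' @param lfc_gene absolute log2FC threshold for the gene panel
#'   (default 1.0).
#' @param min_samples_shared minimum samples a gene must pass in
#'   (default 2).
#' @param top_k_up_vs_tumor cap for vs-tumor upregulated genes
#'   (default 10).
#' @param lfc_floor_down_vs_mac floor for vs-macrophage downregulated genes
#'   (default -2.0).
#' @param include optional curated gene symbols appended with provenance
#'   `"curated"`.
#' @return `data.frame` with `gene`, `category`
#'   (`up_vs_tumor`/`down_vs_tumor`/`up_vs_mac`/`down_vs_mac`/`curated`)
#'   and `n_samples` (samples in which the gene passed). Empty input gives
#'   an empty panel.
#' @export
selectSharedPanel <- function(per_sample,
                              alpha_adj = 0.05,
                              lfc_gene = 1.0,
                              min_samples_shared = 2,
                              top_k_up_vs_tumor = 10,
                              lfc_floor_down_vs_mac = -2.0,
                              include = character()) {
    .assert_scalar_num(min_samples_shared, "min_samples_shared", 1,
                       integer = TRUE)
    empty <- data.frame(gene = character(), category = character(),
                        n_samples = integer(), stringsAsFactors = FALSE)
    if (length(per_sample) == 0) return(empty)

    shared <- function(comparison, direction) {
        per <- lapply(per_sample, function(s)
            .passes(s[[comparison]], alpha_adj, lfc_gene, direction))
        u <- unlist(per)
        if (length(u) == 0) return(character(0))
        tab <- table(u)
        names(tab)[tab >= min_samples_shared]
    }
    min_adj_p <- function(comparison, genes) {
        vapply(genes, function(g) {
            min(vapply(per_sample, function(s) {
                de <- s[[comparison]]
                i <- match(g, de$gene)
                if (is.na(i)) Inf else de$p_adjusted[i]
            }, numeric(1)))
        }, numeric(1))
    }

    up_t <- shared("vs_tumor", "up")
    if (length(up_t) > top_k_up_vs_tumor) {
        p <- min_adj_p("vs_tumor", up_t)
        up_t <- up_t[order(p, up_t)][seq_len(top_k_up_vs_tumor)]
    }
    down_t <- shared("vs_tumor", "down")
    up_m <- shared("vs_mac", "up")
    down_m <- shared("vs_mac", "down")
    if (length(down_m) > 0) {
        keep <- vapply(down_m, function(g) {
            lfcs <- vapply(per_sample, function(s) {
                de <- s$vs_mac
                i <- match(g, de$gene)
                if (is.na(i)) NA_real_ else de$log2fc[i]
            }, numeric(1))
            pass <- !is.na(lfcs) & lfcs <= -lfc_gene
            all(lfcs[pass] <= lfc_floor_down_vs_mac)
        }, logical(1))
        down_m <- down_m[keep]
    }

    n_pass <- function(comparison, direction, genes) {
        vapply(genes, function(g) {
            sum(vapply(per_sample, function(s)
                g %in% .passes(s[[comparison]], alpha_adj, lfc_gene,
                               direction), logical(1)))
        }, integer(1))
    }
    cat_df <- function(genes, category, comparison, direction) {
        if (length(genes) == 0) return(empty)
        data.frame(gene = genes, category = category,
                   n_samples = n_pass(comparison, direction, genes),
                   stringsAsFactors = FALSE)
    }
    panel <- rbind(
        cat_df(up_t, "up_vs_tumor", "vs_tumor", "up"),
        cat_df(down_t, "down_vs_tumor", "vs_tumor", "down"),
        cat_df(up_m, "up_vs_mac", "vs_mac", "up"),
        cat_df(down_m, "down_vs_mac", "vs_mac", "down"))
    if (length(include) > 0)
        panel <- rbind(panel,
                       data.frame(gene = include, category = "curated",
                                  n_samples = NA_integer_,
                                  stringsAsFactors = FALSE))
    rownames(panel) <- NULL
    panel
}

#' Hypergeometric over-representation analysis
#'
#' Standard upper-tail hypergeometric test of a gene list against gene-set
#' collections (e.g. read from a GMT file with [readGmt()]): with universe
#' size `M`, set size `K` (after intersection with the universe), list size
#' `n` and overlap `k`, `p = P(X >= k)` for `X ~ Hypergeometric(M, K, n)`;
#' Benjamini-Hochberg adjustment across sets. Sets disjoint from the
#' universe are reported with `set_size_K = 0` and `p = 1`.
#'
#' @param gene_list character vector of hit genes (subset of `universe`).
#' @param universe character vector of background genes (typically the
#'   genes surviving [qcFilter()] in the sample under test).
#' @param gene_sets named list of character vectors.
#' @return `data.frame` with `set_name`, `overlap_k`, `set_size_K`,
#'   `list_size_n`, `universe_M`, `p_value`, `p_adjusted`.
#' @export
overrepresentation <- function(gene_list, universe, gene_sets) {
    universe <- unique(universe)
    if (length(universe) == 0) stop("empty universe")
    gene_list <- unique(gene_list)
    if (!all(gene_list %in% universe))
        stop("gene_list must be a subset of the universe")
    M <- length(universe)
    n <- length(gene_list)
    res <- lapply(names(gene_sets), function(nm) {
        set <- intersect(unique(gene_sets[[nm]]), universe)
        K <- length(set)
        k <- length(intersect(set, gene_list))
        p <- if (K == 0) 1 else
            stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
        data.frame(set_name = nm, overlap_k = k, set_size_K = K,
                   list_size_n = n, universe_M = M, p_value = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out
}
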