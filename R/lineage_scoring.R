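# Per-gene two-sided Wilcoxon rank-sum DE between two cell sets on the
# log-normalized matrix. log2 fold change follows the convention
# log2(mean(expm1(a)) + 1) - log2(mean(expm1(b)) + 1); adjustment is
# Bonferroni over the tested genes.
.wilcox_de <- function(logm, cells_a, cells_b) {
    a <- as.matrix(logm[, cells_a, drop = FALSE])
    b <- as.matrix(logm[, cells_b, drop = FALSE])
    n_genes <- nrow(a)
    p <- numeric(n_genes)
    for (g in seq_len(n_genes)) {
        p[g] <- suppressWarnings(
            stats::wilcox.test(a[g, ], b[g, ])$p.value)
    }
    p[is.na(p)] <- 1  # constant genes
    ea <- expm1(a); eb <- expm1(b)
    log2fc <- log2(rowMeans(ea) + 1) - log2(rowMeans(eb) + 1)
    data.frame(gene = rownames(logm),
               log2fc = log2fc,
               p_value = p,
               p_adjusted = pmin(p * n_genes, 1),
               pct_a = rowMeans(a > 0),
               pct_b = rowMeans(b > 0),
               row.names = NULL,
               stringsAsFactors = FALSE)
}

# deterministic marker ranking: adjusted p, then |log2fc| (desc), then symbol
.rank_de <- function(de) {
    de[order(de$p_adjusted, -abs(de$log2fc), de$gene), , drop = FALSE]
}

#' Rank lineage marker genes by differential expression
#'
#' Two-sided Wilcoxon rank-sum differential expression between two annotated
#' lineages on the log-normalized matrix, returning the `n_top` genes most
#' upregulated in each group — the gene sets the dual lineage module scores
#' are built from (top 50 by default). Genes are ranked by Bonferroni-
#' adjusted p-value, then absolute log2 fold change, with lexicographic
#' tie-breaks for determinism.
#'
#' @param he a [HybridExperiment-class] with `logcounts`.
#' @param group_a,group_b lineage labels (default the tumor and
#'   macrophage/monocyte annotations).
#' @param annotation_col `colData` column holding per-cell lineage
#'   annotations (default `"cell_type"`).
#' @param n_top markers returned per group (default 50).
#' @return list with `markers_a`, `markers_b` (character vectors) and the
#'   full `de` table (`gene`, `log2fc`, `p_value`, `p_adjusted`, `pct_a`,
#'   `pct_b`; fold changes oriented a-vs-b).
#' @export
rankLineageMarkers <- function(he, group_a = "tumor",
                               group_b = "macrophage",
                               annotation_col = "cell_type", n_top = 50) {
    stopifnot(methods::is(he, "HybridExperiment"))
    ann <- SummarizedExperiment::colData(he)[[annotation_col]]
    if (is.null(ann)) stop("annotation column '", annotation_col,
                           "' not found")
    cells_a <- which(ann == group_a)
    cells_b <- which(ann == group_b)
    if (length(cells_a) < 3 || length(cells_b) < 3)
        stop("each group needs at least 3 cells")
    de <- .wilcox_de(.logcounts(he), cells_a, cells_b)
    up_a <- .rank_de(de[de$log2fc > 0, , drop = FALSE])
    up_b <- .rank_de(de[de$log2fc < 0, , drop = FALSE])
    list(markers_a = utils::head(up_a$gene, n_top),
         markers_b = utils::head(up_b$gene, n_top),
         de = de)
}

#' Binned-control module score
#'
#' Per-cell gene-set score computed against expression-matched controls:
#' genes are cut into `nbin` equal-size bins by their data-wide mean
#' expression; for each gene of the set, `n_ctrl` control genes are drawn
#' uniformly (without replacement) from its bin; the score of a cell is its
#' mean expression over the gene set minus its mean expression over the
#' pooled (unique) control genes. Subtracting bin-matched controls removes
#' the depth/abundance component so scores are comparable across cells, and
#' adding a constant to the whole matrix leaves them unchanged.
#'
#' For very small samples the bins may be too fine; the error suggests
#' lowering `nbin` (e.g. 12 instead of the default 24), which mirrors how
#' the smallest sample of a cohort must be handled.
#'
#' @param he a [HybridExperiment-class] with `logcounts` (or a plain
#'   genes x cells matrix).
#' @param gene_set character vector of gene symbols (must be present).
#' @param nbin number of expression bins (default 24).
#' @param n_ctrl control genes drawn per set gene (default 100; capped at
#'   the bin size).
#' @param seed RNG seed for the control draws.
#' @return named numeric vector, one score per cell.
#' @export
moduleScore <- function(he, gene_set, nbin = 24, n_ctrl = 100, seed = 0) {
    logm <- if (methods::is(he, "HybridExperiment")) .logcounts(he) else he
    .assert_scalar_num(nbin, "nbin", 2, integer = TRUE)
    .assert_scalar_num(n_ctrl, "n_ctrl", 1, integer = TRUE)
    if (length(gene_set) == 0) stop("empty gene_set")
    if (!all(gene_set %in% rownames(logm)))
        stop("gene_set members absent from the matrix: ",
             paste(utils::head(setdiff(gene_set, rownames(logm)), 5),
                   collapse = ", "))
    n_genes <- nrow(logm)
    if (nbin > n_genes)
        stop("nbin (", nbin, ") exceeds the number of genes (", n_genes,
             "); lower nbin (e.g. 12)")
    means <- Matrix::rowMeans(logm)
    rk <- rank(means, ties.method = "first")
    bin <- floor((rk - 1) * nbin / n_genes) + 1L
    names(bin) <- rownames(logm)
    ctrl <- .with_seed(seed, {
        unique(unlist(lapply(gene_set, function(g) {
            members <- names(bin)[bin == bin[[g]]]
            sample(members, min(n_ctrl, length(members)))
        })))
    })
    score <- Matrix::colMeans(logm[gene_set, , drop = FALSE]) -
        Matrix::colMeans(logm[ctrl, , drop = FALSE])
    stats::setNames(as.numeric(score), colnames(logm))
}

#' Compute the dual lineage module scores
#'
#' Convenience wrapper computing the tumor-program score (`tum_score`) and
#' macrophage/monocyte-program score (`mac_score`) from the two marker lists
#' (typically the top-50 lists of [rankLineageMarkers()]) and storing them
#' in `colData`.
#'
#' @param he a [HybridExperiment-class] with `logcounts`.
#' @param markers_tum,markers_mac marker gene sets for the two programs.
#' @inheritParams moduleScore
#' @return the input with `tum_score` and `mac_score` columns added.
#' @export
scoreLineages <- function(he, markers_tum, markers_mac, nbin = 24,
                          n_ctrl = 100, seed = 0) {
    stopifnot(methods::is(he, "HybridExperiment"))
    cd <- SummarizedExperiment::colData(he)
    cd$tum_score <- moduleScore(he, markers_tum, nbin, n_ctrl, seed)
    cd$mac_score <- moduleScore(he, markers_mac, nbin, n_ctrl, seed)
    SummarizedExperiment::colData(he) <- cd
    he
}
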