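# small in-code fixtures shared across test files

make_he <- function(mat, ...) {
    if (is.null(rownames(mat)))
        rownames(mat) <- sprintf("G%03d", seq_len(nrow(mat)))
    if (is.null(colnames(mat)))
        colnames(mat) <- sprintf("C%03d", seq_len(ncol(mat)))
    HybridExperiment(Matrix::Matrix(mat, sparse = TRUE), ...)
}

# HybridExperiment with injected clusters, scores and annotations, for
# testing the cluster-level decision rules without a full pipeline
make_scored_he <- function(cluster, cell_type, tum_score, mac_score) {
    n <- length(cluster)
    mat <- matrix(rpois(5 * n, 5), nrow = 5)
    he <- make_he(mat)
    cd <- SummarizedExperiment::colData(he)
    cd$cluster <- factor(cluster)
    cd$cell_type <- cell_type
    cd$tum_score <- tum_score
    cd$mac_score <- mac_score
    SummarizedExperiment::colData(he) <- cd
    he
}

# Poisson background counts with optional per-group elevated genes
make_group_counts <- function(n_genes, groups, elevated = list(),
                              base_lambda = 2, fold = 8, seed = 1) {
    set.seed(seed)
    n <- length(groups)
    mat <- matrix(rpois(n_genes * n, base_lambda), nrow = n_genes,
                  dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                  sprintf("C%03d", seq_len(n))))
    for (g in names(elevated)) {
        idx <- which(groups == g)
        genes <- elevated[[g]]
        mat[genes, idx] <- matrix(
            rpois(length(genes) * length(idx), base_lambda * fold),
            nrow = length(genes))
    }
    mat
}

# ten-cell fixture with hand-computable gating outcomes (threshold 150,
# inclusive)
cycif_fixture <- function() {
    markers <- c("CD45", "MITF", "TYR", "MLANA", "GP100", "HTR2B",
                 "CD25", "CD203c", "TMSB10", "CD74", "GPX1")
    lo <- 50; hi <- 500
    rows <- list(
        h1 = c(hi, lo, lo, hi, lo, lo, lo, lo, hi, lo, hi),  # hybrid
        h2 = c(hi, hi, lo, lo, lo, hi, lo, lo, lo, hi, lo),  # hybrid
        h3 = c(hi, lo, lo, lo, lo, hi, lo, lo, 150, lo, lo), # HTR2B-only but
                                                             # CD25-: hybrid
        x1 = c(hi, lo, lo, lo, lo, hi, hi, lo, hi, hi, hi),  # excluded
        x2 = c(hi, lo, lo, lo, lo, hi, lo, hi, lo, lo, lo),  # excluded
        t1 = c(lo, hi, hi, lo, lo, lo, lo, lo, hi, lo, lo),  # tumor
        t2 = c(lo, lo, lo, lo, hi, lo, lo, lo, lo, hi, lo),  # tumor
        t3 = c(lo, lo, lo, lo, lo, hi, lo, lo, lo, lo, 150), # tumor
        o1 = c(hi, lo, lo, lo, lo, lo, lo, lo, hi, hi, hi),  # CD45 only
        o2 = c(lo, lo, lo, lo, lo, lo, lo, lo, lo, lo, lo))  # negative
    tab <- as.data.frame(do.call(rbind, rows))
    colnames(tab) <- markers
    cbind(data.frame(cell_id = names(rows), stringsAsFactors = FALSE), tab)
}

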