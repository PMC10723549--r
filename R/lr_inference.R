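#' Bundled ligand-receptor pair table
#'
#' A miniature ligand-receptor pair table containing tumor-macrophage
#' signaling axes with established roles in metastasis (GAS6-AXL,
#' CXCL12-CXCR4, LGALS9-P4HB, IGF1-IGF1R, TYROBP-CD44, APP-CD74, ANXA1-FPR1
#' and ANXA1-FPR3), matching genes planted by the synthetic generator.
#'
#' @return `data.frame` with columns `ligand`, `receptor`, `annotation`.
#' @export
lrPairsExample <- function() {
    path <- system.file("extdata", "lr_pairs.csv", package = "scHybrid",
                        mustWork = TRUE)
    utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Permutation-based ligand-receptor interaction inference
#'
#' Scores putative cell-cell communication between every ordered pair of
#' cell types: the interaction mean of a ligand-receptor pair for
#' (sender, receiver) is `(mean ligand expression in sender cells + mean
#' receptor expression in receiver cells) / 2` on the log-normalized
#' matrix. Significance comes from a label-permutation null: cell-type
#' labels are shuffled `n_permutations` times (seeded) and
#' `p = #(permuted mean >= observed) / n_permutations` (no smoothing).
#'
#' Filters follow the statistical-inference-of-specificity convention:
#' cell types with fewer than `min_cells_per_type` cells are dropped before
#' anything else (permutations are restricted to the retained cells, so
#' dropping a type never changes results among the remaining types), and a
#' pair x (sender, receiver) combination is evaluated only if the ligand is
#' expressed in at least `min_expr_fraction` of sender cells and the
#' receptor in at least `min_expr_fraction` of receiver cells. Pairs whose
#' genes are absent from the matrix are skipped (recorded in
#' `attr(result, "skipped_pairs")`).
#'
#' @param he a [HybridExperiment-class] with `logcounts`.
#' @param pairs `data.frame` with columns `ligand` and `receptor`.
#' @param labels per-cell type labels (default: `colData` column
#'   `cell_type`, with cells of hybrid clusters best relabeled `"hybrid"`
#'   by the caller beforehand).
#' @param n_permutations permutations for the null (default 1000).
#' @param alpha significance threshold, applied as `p <= alpha`
#'   (default 0.05).
#' @param min_cells_per_type minimum cells per retained type (default 20).
#' @param min_expr_fraction expression-fraction filter (default 0.1).
#' @param seed integer RNG seed.
#' @return `data.frame` of evaluated combinations: `ligand`, `receptor`,
#'   `sender`, `receiver`, `interaction_mean`, `p_value`, `significant`.
#' @export
inferInteractions <- function(he, pairs, labels = NULL,
                              n_permutations = 1000, alpha = 0.05,
                              min_cells_per_type = 20,
                              min_expr_fraction = 0.1, seed = 0) {
    stopifnot(methods::is(he, "HybridExperiment"))
    if (!all(c("ligand", "receptor") %in% colnames(pairs)))
        stop("'pairs' needs columns 'ligand' and 'receptor'")
    .assert_scalar_num(n_permutations, "n_permutations", 1, integer = TRUE)
    .assert_scalar_num(alpha, "alpha", 0, 1)
    if (is.null(labels))
        labels <- SummarizedExperiment::colData(he)$cell_type
    if (length(labels) != ncol(he)) stop("labels must cover all cells")
    logm <- .logcounts(he)

    keep_types <- names(which(table(labels) >= min_cells_per_type))
    if (length(keep_types) < 2)
        stop("fewer than 2 cell types with >= ", min_cells_per_type,
             " cells")
    keep <- labels %in% keep_types
    labels <- factor(labels[keep], levels = keep_types)
    logm <- logm[, keep, drop = FALSE]

    present <- pairs$ligand %in% rownames(logm) &
        pairs$receptor %in% rownames(logm)
    skipped <- pairs[!present, , drop = FALSE]
    pairs <- pairs[present, , drop = FALSE]
    if (nrow(pairs) == 0) stop("no ligand-receptor pair present in matrix")

    genes <- unique(c(pairs$ligand, pairs$receptor))
    expr <- as.matrix(logm[genes, , drop = FALSE])

    # observed per-type means and expression fractions
    grp <- lapply(keep_types, function(t) which(labels == t))
    names(grp) <- keep_types
    mean_by <- function(e, groups) {
        m <- vapply(groups, function(i)
            rowMeans(e[, i, drop = FALSE]), numeric(nrow(e)))
        matrix(m, nrow = nrow(e),
               dimnames = list(rownames(e), names(groups)))
    }
    obs_mean <- mean_by(expr, grp)          # genes x types
    obs_frac <- vapply(grp, function(i)
        rowMeans(expr[, i, drop = FALSE] > 0), numeric(nrow(expr)))
    rownames(obs_mean) <- rownames(obs_frac) <- genes

    combos <- expand.grid(pair = seq_len(nrow(pairs)),
                          sender = keep_types, receiver = keep_types,
                          stringsAsFactors = FALSE)
    lig <- pairs$ligand[combos$pair]
    rec <- pairs$receptor[combos$pair]
    eval_ok <- obs_frac[cbind(lig, combos$sender)] >= min_expr_fraction &
        obs_frac[cbind(rec, combos$receiver)] >= min_expr_fraction
    combos <- combos[eval_ok, , drop = FALSE]
    lig <- lig[eval_ok]; rec <- rec[eval_ok]
    if (nrow(combos) == 0) stop("no combination passes the expression filter")

    observed <- (obs_mean[cbind(lig, combos$sender)] +
                 obs_mean[cbind(rec, combos$receiver)]) / 2

    exceed <- numeric(nrow(combos))
    .with_seed(seed, {
        n_cells <- ncol(expr)
        for (b in seq_len(n_permutations)) {
            perm <- labels[sample.int(n_cells)]
            pg <- lapply(keep_types, function(t) which(perm == t))
            pm <- mean_by(expr, pg)
            rownames(pm) <- genes
            colnames(pm) <- keep_types
            permuted <- (pm[cbind(lig, combos$sender)] +
                         pm[cbind(rec, combos$receiver)]) / 2
            exceed <- exceed + (permuted >= observed)
        }
    })
    p <- exceed / n_permutations
    out <- data.frame(ligand = lig, receptor = rec,
                      sender = combos$sender, receiver = combos$receiver,
                      interaction_mean = observed, p_value = p,
                      significant = p <= alpha,
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "skipped_pairs") <- skipped
    out
}

#' Count significant interactions per sender/receiver pair
#'
#' @param results output of [inferInteractions()].
#' @param alpha significance threshold (default: reuse the stored
#'   `significant` flags when `NULL`).
#' @return integer matrix, senders x receivers; the grand total equals the
#'   number of significant results.
#' @export
summarizeInteractions <- function(results, alpha = NULL) {
    types <- sort(unique(c(results$sender, results$receiver)))
    m <- matrix(0L, length(types), length(types),
                dimnames = list(sender = types, receiver = types))
    sig <- if (is.null(alpha)) results$significant else
        results$p_value <= alpha
    if (any(sig)) {
        tab <- table(results$sender[sig], results$receiver[sig])
        m[rownames(tab), colnames(tab)] <-
            m[rownames(tab), colnames(tab)] + as.matrix(tab)
    }
    m
}
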