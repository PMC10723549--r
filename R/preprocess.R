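#' Gene-level QC filter
#'
#' Retains genes detected (nonzero) in at least `min_cells` cells; the cell
#' set is unchanged. This is the only gene filter applied before
#' normalization (`min.cell = 3` is the loading default of the droplet
#' workflow this package follows).
#'
#' @param he a [HybridExperiment-class].
#' @param min_cells minimum number of cells with nonzero counts.
#' @return the filtered `HybridExperiment`.
#' @export
qcFilter <- function(he, min_cells = 3) {
    stopifnot(methods::is(he, "HybridExperiment"))
    .assert_scalar_num(min_cells, "min_cells", 0, integer = TRUE)
    if (ncol(he) == 0L || nrow(he) == 0L) stop("empty count matrix")
    if (min_cells == 0) return(he)
    n_detect <- Matrix::rowSums(.counts(he) > 0)
    he[n_detect >= min_cells, ]
}

# column-normalize a genes x cells sparse matrix to log1p(scale * count/total)
.log_norm <- function(m, scale = 1e4) {
    totals <- Matrix::colSums(m)
    if (any(totals == 0))
        stop("cell(s) with zero total counts: ",
             paste(utils::head(colnames(m)[totals == 0], 5), collapse = ", "))
    m <- methods::as(m, "CsparseMatrix")
    fac <- rep.int(scale / totals, diff(m@p))
    m@x <- log1p(m@x * fac)
    m
}

#' Log-normalize counts
#'
#' Library-size normalization to `scale` counts per cell followed by
#' `log(1 + x)`: `log1p(scale * count / cell_total)`. Zeros map to zero and
#' the transform is monotone within a cell, so the sparsity pattern is
#' preserved exactly. Stored as a `logcounts` assay.
#'
#' @param he a [HybridExperiment-class].
#' @param scale target library size (default `1e4`, i.e. counts per 10k).
#' @return the input with a `logcounts` assay added.
#' @export
logNormalize <- function(he, scale = 1e4) {
    stopifnot(methods::is(he, "HybridExperiment"))
    .assert_scalar_num(scale, "scale", lower = 1e-8)
    SummarizedExperiment::assay(he, "logcounts") <-
        .log_norm(.counts(he), scale)
    he
}

# top-n highly variable genes by dispersion (var/mean) of the normalized
# (expm1 of logcounts) values
.hvg <- function(logm, n_hvg) {
    n <- nrow(logm)
    if (n_hvg >= n) return(rownames(logm))
    e <- expm1(logm)
    mu <- Matrix::rowMeans(e)
    v <- Matrix::rowMeans(e^2) - mu^2
    disp <- ifelse(mu > 0, v / mu, 0)
    rownames(logm)[order(disp, decreasing = TRUE)[seq_len(n_hvg)]]
}

#' Select principal components by the cumulative/individual variance rule
#'
#' The retained PC set is the smallest prefix whose cumulative variance
#' ratio (over the computed PCs) exceeds `cum_threshold`, restricted to PCs
#' whose individual ratio is at least `indiv_threshold`. Because ratios are
#' non-increasing the result is again a prefix. Fallbacks guarantee a usable
#' embedding: if the restriction removes everything, the first
#' `min(fallback, K)` PCs are used (matching the `PCs = 1:10` convention of
#' the doublet scorers); if a single PC survives, two are used.
#'
#' @param variance_ratio non-increasing per-PC variance proportions.
#' @param cum_threshold cumulative-variance threshold (default 0.95).
#' @param indiv_threshold individual-variance threshold (default 0.05).
#' @param fallback prefix length used when no PC passes both rules.
#' @return number of selected PCs (a prefix length).
#' @examples
#' selectPCs(c(0.60, 0.20, 0.10, 0.06, 0.02, 0.02))  # 4
#' @export
selectPCs <- function(variance_ratio, cum_threshold = 0.95,
                      indiv_threshold = 0.05, fallback = 10) {
    r <- variance_ratio
    if (length(r) == 0 || any(!is.finite(r)) || any(r < 0))
        stop("invalid variance ratios")
    K <- length(r)
    cum <- cumsum(r)
    prefix <- if (any(cum > cum_threshold))
        which(cum > cum_threshold)[1] else K
    sel <- seq_len(prefix)
    sel <- sel[r[sel] >= indiv_threshold]
    n <- length(sel)
    if (n == 0) n <- min(fallback, K)
    else if (n == 1) n <- min(2L, K)
    n
}

# PCA of cells over the given genes (centered, unit-scaled); truncated SVD
# for large problems. Returns cells x K scores plus variance ratios over the
# computed PCs.
.pca_embed <- function(logm, genes, max_pcs, seed = 0) {
    x <- as.matrix(Matrix::t(logm[genes, , drop = FALSE]))
    sds <- apply(x, 2, stats::sd)
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) == 0) stop("degenerate expression matrix (no variable genes)")
    k <- min(max_pcs, nrow(x) - 1L, ncol(x))
    if (k < 2) stop("need at least 3 cells and 2 variable genes for PCA")
    pc <- .with_seed(seed, {
        if (k < min(dim(x)) / 3 && min(dim(x)) > 50)
            irlba::prcomp_irlba(x, n = k, center = TRUE, scale. = TRUE)
        else
            stats::prcomp(x, rank. = k, center = TRUE, scale. = TRUE)
    })
    scores <- pc$x[, seq_len(k), drop = FALSE]
    rownames(scores) <- colnames(logm)
    ratio <- pc$sdev[seq_len(k)]^2 / sum(pc$sdev[seq_len(k)]^2)
    list(pcs = scores, variance_ratio = ratio)
}

#' Embed cells by PCA on highly variable genes
#'
#' Selects `n_hvg` highly variable genes (dispersion of the normalized
#' values), centers and unit-scales them, computes up to `max_pcs` principal
#' components, and applies the [selectPCs()] rule (cumulative variance
#' > `cum_threshold`, individual variance >= `indiv_threshold`) to fix the
#' embedding dimension used by clustering.
#'
#' @param he a [HybridExperiment-class] with a `logcounts` assay.
#' @param n_hvg number of highly variable genes (all genes if fewer).
#' @param max_pcs number of PCs to compute.
#' @param cum_threshold,indiv_threshold see [selectPCs()].
#' @param seed seed for the truncated SVD initialization.
#' @return the input with `reducedDim(x, "PCA")` set (all computed PCs) and
#'   `metadata(x)$pca` holding `variance_ratio` and `n_selected`.
#' @export
embedCells <- function(he, n_hvg = 2000, max_pcs = 50,
                       cum_threshold = 0.95, indiv_threshold = 0.05,
                       seed = 0) {
    stopifnot(methods::is(he, "HybridExperiment"))
    if (ncol(he) < 3) stop("need at least 3 cells")
    logm <- .logcounts(he)
    genes <- .hvg(logm, n_hvg)
    emb <- .pca_embed(logm, genes, max_pcs, seed = seed)
    n_sel <- selectPCs(emb$variance_ratio, cum_threshold, indiv_threshold,
                       fallback = min(10, max_pcs))
    SingleCellExperiment::reducedDim(he, "PCA") <- emb$pcs
    S4Vectors::metadata(he)$pca <- list(variance_ratio = emb$variance_ratio,
                                        n_selected = n_sel,
                                        hvg = genes)
    he
}

# shared-nearest-neighbor graph in the given embedding: cells are connected
# when either lists the other among its k nearest neighbors, with Jaccard
# overlap of their neighbor sets as edge weight (edges below `prune` are
# dropped) -- the standard construction for Leiden/Louvain clustering of
# scRNA-seq embeddings
.knn_graph <- function(pcs, k, prune = 1 / 15) {
    idx <- BiocNeighbors::findKNN(pcs, k = k)$index
    n <- nrow(pcs)
    # neighbor sets include the cell itself, as in the SNN convention
    nbr <- Matrix::sparseMatrix(
        i = c(seq_len(n), rep(seq_len(n), k)),
        j = c(seq_len(n), as.vector(idx)),
        x = 1, dims = c(n, n))
    shared <- Matrix::tcrossprod(nbr)          # |N(i) & N(j)|
    jac <- methods::as(shared, "TsparseMatrix")
    keep <- jac@i < jac@j
    i <- jac@i[keep] + 1L; j <- jac@j[keep] + 1L
    w <- jac@x[keep] / (2 * (k + 1) - jac@x[keep])
    ok <- w >= prune
    igraph::graph_from_data_frame(
        data.frame(from = i[ok], to = j[ok], weight = w[ok]),
        directed = FALSE,
        vertices = data.frame(name = seq_len(n)))
}

#' Cluster cells with the Leiden algorithm
#'
#' Builds a k-nearest-neighbor graph over the selected principal components
#' (Euclidean distance) and partitions it with the Leiden algorithm
#' (modularity objective) at the given resolution. Every cell receives
#' exactly one label; results are deterministic for a fixed seed.
#'
#' @param he a [HybridExperiment-class] processed by [embedCells()].
#' @param k_neighbors neighbors per cell for the graph (default 20).
#' @param resolution Leiden resolution parameter (default 1.0).
#' @param seed integer RNG seed (default 0).
#' @param umap also compute 2-d UMAP coordinates (requires the `uwot`
#'   package; Euclidean distance).
#' @return the input with `colData(x)$cluster` set (factor) and, if
#'   requested, `reducedDim(x, "UMAP")`.
#' @export
clusterCells <- function(he, k_neighbors = 20, resolution = 1.0, seed = 0,
                         umap = FALSE) {
    stopifnot(methods::is(he, "HybridExperiment"))
    .assert_scalar_num(k_neighbors, "k_neighbors", 1, integer = TRUE)
    if (k_neighbors >= ncol(he))
        stop("k_neighbors must be smaller than the number of cells")
    if (!"PCA" %in% SingleCellExperiment::reducedDimNames(he))
        stop("no PCA embedding; run embedCells() first")
    n_sel <- S4Vectors::metadata(he)$pca$n_selected
    pcs <- SingleCellExperiment::reducedDim(he, "PCA")[,
        seq_len(n_sel), drop = FALSE]
    membership <- .with_seed(seed, {
        g <- .knn_graph(pcs, k_neighbors)
        igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution)$membership
    })
    SummarizedExperiment::colData(he)$cluster <- factor(membership)
    if (umap) {
        if (!requireNamespace("uwot", quietly = TRUE))
            stop("UMAP requires the 'uwot' package")
        um <- .with_seed(seed,
            uwot::umap(pcs, metric = "euclidean", n_threads = 1))
        dimnames(um) <- list(colnames(he), c("UMAP1", "UMAP2"))
        SingleCellExperiment::reducedDim(he, "UMAP") <- um
    }
    he
}
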