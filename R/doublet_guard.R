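#' Doublet-scoring configuration
#'
#' Parameters of the three simulation-based doublet scores. `pN` and `pK`
#' follow the conventions of the pANN ("proportion of artificial nearest
#' neighbors") scorer: artificial doublets make up `pN` of the merged
#' (observed + artificial) set, i.e. `n_art = round(pN/(1-pN) * n_obs)`,
#' and the neighborhood size is `K = round(pK * n_merged)`. `n_sim`
#' artificial doublets (default: one per observed cell) and `k_sim`
#' neighbors (default: `round(0.5 * sqrt(n_merged))`) parameterize the
#' kNN-fraction and kNN-density scores. `nExp`, the expected doublet count
#' a hard classification would use, is recorded for provenance but unused:
#' the consensus rule ranks clusters instead of thresholding cells.
#'
#' @param n_pcs principal components of the merged embedding (default 10).
#' @param pN artificial-doublet proportion of the merged set (default 0.25).
#' @param pK neighborhood size as a fraction of the merged set
#'   (default 0.09).
#' @param nExp optional expected-doublet count (recorded only).
#' @param n_sim artificial doublets for the kNN-fraction/density scores
#'   (`NULL`: one per observed cell).
#' @param k_sim neighbors for those scores (`NULL`: `round(0.5*sqrt(n))`).
#' @param n_hvg highly variable genes for the merged embedding.
#' @param seed integer RNG seed.
#' @return a list of class `DoubletConfig`.
#' @export
doubletConfig <- function(n_pcs = 10, pN = 0.25, pK = 0.09, nExp = NULL,
                          n_sim = NULL, k_sim = NULL, n_hvg = 2000,
                          seed = 0) {
    .assert_scalar_num(n_pcs, "n_pcs", 2, integer = TRUE)
    .assert_scalar_num(pN, "pN", lower = 1e-8)
    if (pN >= 1) stop("'pN' must be < 1")
    .assert_scalar_num(pK, "pK", 1e-8, 1)
    .assert_scalar_num(seed, "seed", integer = TRUE)
    structure(list(n_pcs = n_pcs, pN = pN, pK = pK, nExp = nExp,
                   n_sim = n_sim, k_sim = k_sim, n_hvg = n_hvg,
                   seed = as.integer(seed)),
              class = "DoubletConfig")
}

# simulation-size conventions of the pANN scorer
.n_artificial <- function(pN, n_obs) round(pN / (1 - pN) * n_obs)
.pann_k <- function(pK, n_merged) round(pK * n_merged)

#' Simulate artificial doublets from observed libraries
#'
#' Each artificial profile is the element-wise sum of two distinct,
#' randomly chosen observed columns — the same generative definition the
#' spiked ground-truth doublets follow. The chosen parent column indices
#' are recorded in `attr(, "parents")`.
#'
#' @param counts genes x cells count matrix (or a
#'   [HybridExperiment-class]).
#' @param n_art number of artificial doublets.
#' @param seed integer RNG seed.
#' @return sparse genes x `n_art` count matrix with columns `ART#`.
#' @export
simulateArtificialDoublets <- function(counts, n_art, seed = 0) {
    if (methods::is(counts, "HybridExperiment")) counts <- .counts(counts)
    n_obs <- ncol(counts)
    if (n_obs < 2) stop("need at least 2 observed cells")
    .assert_scalar_num(n_art, "n_art", 1, integer = TRUE)
    .with_seed(seed, {
        p1 <- sample.int(n_obs, n_art, replace = TRUE)
        p2 <- vapply(p1, function(i) {
            j <- sample.int(n_obs - 1L, 1L)
            if (j >= i) j + 1L else j
        }, integer(1))
        art <- counts[, p1, drop = FALSE] + counts[, p2, drop = FALSE]
        colnames(art) <- sprintf("ART%05d", seq_len(n_art))
        attr(art, "parents") <- cbind(p1, p2)
        art
    })
}

# embed merged observed+artificial counts: log-normalize, HVG, PCA
.merged_embedding <- function(obs, art, n_pcs, n_hvg, seed) {
    merged <- methods::cbind2(obs, art)
    logm <- .log_norm(merged)
    genes <- .hvg(logm, n_hvg)
    .pca_embed(logm, genes, max_pcs = n_pcs, seed = seed)$pcs
}

# pANN: fraction of artificial cells among the K nearest neighbors of each
# observed cell in the merged embedding (rows 1..n_obs observed, the rest
# artificial; self excluded)
.pann_from_embedding <- function(emb, n_obs, K) {
    if (K < 1) stop("neighborhood K < 1; increase pK")
    is_art <- c(rep(FALSE, n_obs), rep(TRUE, nrow(emb) - n_obs))
    nn <- suppressWarnings(BiocNeighbors::queryKNN(
        emb, emb[seq_len(n_obs), , drop = FALSE], k = K + 1L))$index
    vapply(seq_len(n_obs), function(i) {
        idx <- setdiff(nn[i, ], i)[seq_len(K)]
        mean(is_art[idx])
    }, numeric(1))
}

# kNN-fraction score (artificial-neighbor fraction corrected for the
# simulation ratio) and kNN-radius density ratio, sharing one embedding
.sim_scores_from_embedding <- function(emb, n_obs, k_sim) {
    n_art <- nrow(emb) - n_obs
    is_art <- c(rep(FALSE, n_obs), rep(TRUE, n_art))
    obs_emb <- emb[seq_len(n_obs), , drop = FALSE]
    art_emb <- emb[-seq_len(n_obs), , drop = FALSE]
    r <- n_art / n_obs

    nn <- suppressWarnings(
        BiocNeighbors::queryKNN(emb, obs_emb, k = k_sim + 1L))$index
    knn_fraction <- vapply(seq_len(n_obs), function(i) {
        idx <- setdiff(nn[i, ], i)[seq_len(k_sim)]
        f <- mean(is_art[idx])
        (f / r) / (f / r + (1 - f))
    }, numeric(1))

    nn_obs <- suppressWarnings(
        BiocNeighbors::queryKNN(obs_emb, obs_emb, k = k_sim + 1L))
    radius <- nn_obs$distance[, k_sim + 1L]
    hits <- suppressWarnings(BiocNeighbors::queryNeighbors(
        art_emb, obs_emb, threshold = radius))$index
    density_ratio <- (lengths(hits) / n_art) / (k_sim / n_obs)
    list(knn_fraction = knn_fraction, density_ratio = density_ratio)
}

#' Compute the three simulation-based doublet scores
#'
#' Artificial doublets are simulated, merged with the observed cells,
#' embedded (log-normalization, highly variable genes, `n_pcs` principal
#' components) and scored with kNN statistics:
#'
#' * `pann` — proportion of artificial cells among the `K = round(pK *
#'   n_merged)` nearest neighbors of each observed cell;
#' * `knn_fraction` — artificial-neighbor fraction `f` over `k_sim`
#'   neighbors, corrected for the simulation ratio `r = n_art/n_obs`:
#'   `(f/r) / (f/r + (1-f))`;
#' * `density_ratio` — kNN-radius density of artificial cells (per
#'   simulated cell) over the density of observed cells (per observed
#'   cell) around each observed cell.
#'
#' The scorers are contract-level reimplementations of the published
#' simulation-based family (pANN-, kNN-fraction- and kNN-density-style);
#' downstream adjudication depends only on their consensus ranking.
#'
#' @param he a [HybridExperiment-class].
#' @param config a [doubletConfig()].
#' @return the input with `pann`, `knn_fraction`, `density_ratio` columns in
#'   `colData` (also retrievable via [doubletScores()]).
#' @export
scoreDoublets <- function(he, config = doubletConfig()) {
    stopifnot(methods::is(he, "HybridExperiment"),
              inherits(config, "DoubletConfig"))
    obs <- .counts(he)
    n_obs <- ncol(obs)
    if (n_obs < 3) stop("need at least 3 observed cells")

    ## pANN-style score
    n_art1 <- .n_artificial(config$pN, n_obs)
    art1 <- simulateArtificialDoublets(obs, n_art1, seed = config$seed)
    emb1 <- .merged_embedding(obs, art1, config$n_pcs, config$n_hvg,
                              config$seed)
    pann <- .pann_from_embedding(emb1, n_obs,
                                 .pann_k(config$pK, n_obs + n_art1))

    ## shared embedding for the kNN-fraction and kNN-density scores
    n_art2 <- if (is.null(config$n_sim)) n_obs else config$n_sim
    art2 <- simulateArtificialDoublets(obs, n_art2, seed = config$seed + 1L)
    emb2 <- .merged_embedding(obs, art2, config$n_pcs, config$n_hvg,
                              config$seed)
    k_sim <- if (is.null(config$k_sim))
        max(2L, round(0.5 * sqrt(n_obs + n_art2))) else config$k_sim
    sim <- .sim_scores_from_embedding(emb2, n_obs, k_sim)

    cd <- SummarizedExperiment::colData(he)
    cd$pann <- pann
    cd$knn_fraction <- sim$knn_fraction
    cd$density_ratio <- sim$density_ratio
    SummarizedExperiment::colData(he) <- cd
    S4Vectors::metadata(he)$doublet_config <- config
    he
}

#' Cluster-level doublet adjudication (consensus rule)
#'
#' Per cluster and per scoring method, takes the median score and its
#' percentile rank among cluster medians (fraction of other clusters with a
#' strictly smaller median, so tied clusters share the lower rank). A
#' cluster is flagged as a doublet artifact when its rank exceeds
#' `rank_threshold` in at least 2 of the 3 methods — the operational
#' reading of "consistently elevated doublet scores compared to the
#' majority of clusters". Flagged clusters that were called hybrid are
#' demoted (`is_hybrid` set to `FALSE`, reason recorded); when run before
#' [callHybridClusters()], the flags additionally remove artifact clusters
#' from the calling comparison families.
#'
#' @param he a [HybridExperiment-class] with clusters and doublet scores.
#' @param rank_threshold percentile-rank threshold (default 0.8).
#' @return the input with `metadata(x)$doublet_adjudication` set and any
#'   existing hybrid-call table updated.
#' @export
adjudicateClusters <- function(he, rank_threshold = 0.8) {
    stopifnot(methods::is(he, "HybridExperiment"))
    .assert_scalar_num(rank_threshold, "rank_threshold", 0, 1)
    cl <- clusterLabels(he)
    sc <- doubletScores(he)
    if (is.null(cl)) stop("no cluster labels")
    if (is.null(sc)) stop("no doublet scores; run scoreDoublets() first")
    ks <- levels(cl)
    methodcols <- c("pann", "knn_fraction", "density_ratio")
    med <- sapply(methodcols, function(m)
        vapply(ks, function(k) stats::median(sc[[m]][cl == k]), numeric(1)))
    med <- matrix(med, nrow = length(ks),
                  dimnames = list(ks, methodcols))
    if (length(ks) < 2) {
        warning("single cluster: doublet comparison impossible; not flagged")
        rk <- med * 0
    } else {
        rk <- apply(med, 2, function(v)
            vapply(v, function(x) sum(v < x), numeric(1)) /
                (length(v) - 1))
    }
    n_elev <- rowSums(rk > rank_threshold)
    adj <- data.frame(cluster = ks,
                      median_pann = med[, "pann"],
                      median_knn_fraction = med[, "knn_fraction"],
                      median_density_ratio = med[, "density_ratio"],
                      rank_pann = rk[, "pann"],
                      rank_knn_fraction = rk[, "knn_fraction"],
                      rank_density_ratio = rk[, "density_ratio"],
                      n_methods_elevated = n_elev,
                      flagged_doublet = n_elev >= 2,
                      row.names = NULL, stringsAsFactors = FALSE)
    S4Vectors::metadata(he)$doublet_adjudication <- adj
    calls <- hybridCalls(he)
    if (!is.null(calls)) {
        demote <- calls$is_hybrid &
            calls$cluster %in% adj$cluster[adj$flagged_doublet]
        calls$is_hybrid[demote] <- FALSE
        calls$demoted[demote] <- TRUE
        calls$reason[demote] <-
            "doublet consensus: percentile rank above threshold in >= 2 methods"
        S4Vectors::metadata(he)$hybrid_calls <- calls
    }
    he
}
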