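test_that("artificial doublets are parent sums with the pANN size convention", {
    set.seed(8)
    m <- matrix(rpois(50 * 40, 3), nrow = 50,
                dimnames = list(sprintf("G%02d", 1:50),
                                sprintf("C%02d", 1:40)))
    art <- simulateArtificialDoublets(m, n_art = 15, seed = 1)
    expect_equal(ncol(art), 15)
    par <- attr(art, "parents")
    for (i in 1:15) {
        expect_equal(as.numeric(art[, i]),
                     as.numeric(m[, par[i, 1]] + m[, par[i, 2]]))
        expect_true(par[i, 1] != par[i, 2])
    }
    # identical seed, identical artificial set
    art2 <- simulateArtificialDoublets(m, n_art = 15, seed = 1)
    expect_identical(as.matrix(art), as.matrix(art2))
    # size conventions: pN of the merged set; K from pK of the merged set
    expect_equal(scHybrid:::.n_artificial(0.25, 300), 100)
    expect_equal(scHybrid:::.pann_k(0.09, 400), 36)
})

test_that("kNN doublet scores behave correctly on planted geometries", {
    # observed cell 1 sits inside a dense ball of artificial cells, far
    # from the other observed cells
    set.seed(5)
    obs <- rbind(c(0, 0), matrix(rnorm(38, mean = 30), ncol = 2))
    art <- matrix(rnorm(80, mean = 0, sd = 0.1), ncol = 2)
    emb <- rbind(obs, art)
    pann <- scHybrid:::.pann_from_embedding(emb, n_obs = nrow(obs), K = 10)
    expect_equal(pann[1], 1.0)   # all K neighbors artificial
    sim <- scHybrid:::.sim_scores_from_embedding(emb, n_obs = nrow(obs),
                                                 k_sim = 10)
    expect_gt(sim$density_ratio[1], 1)
    # a cell far from every artificial profile scores zero
    expect_equal(sim$knn_fraction[20], 0)
    expect_true(all(pann >= 0 & pann <= 1))
    expect_true(all(sim$knn_fraction >= 0 & sim$knn_fraction <= 1))
    expect_true(all(sim$density_ratio >= 0))
})

test_that("scoreDoublets is deterministic and bounded", {
    he <- simulateCounts(simConfig(populations = c(tumor = 120,
                                                   macrophage = 80),
                                   n_genes = 500, seed = 12))
    he <- spikeDoublets(he, rate = 0.1, seed = 12)
    cfg <- doubletConfig(n_pcs = 5, seed = 3)
    s1 <- doubletScores(scoreDoublets(he, cfg))
    s2 <- doubletScores(scoreDoublets(he, cfg))
    expect_identical(s1, s2)
    expect_true(all(s1$pann >= 0 & s1$pann <= 1))
    expect_true(all(s1$knn_fraction >= 0 & s1$knn_fraction <= 1))
    expect_true(all(s1$density_ratio >= 0))
    expect_true(all(is.finite(unlist(s1[-1]))))
})

test_that("cluster adjudication uses tie-sharing percentile ranks", {
    # two clusters with identical score distributions: neither flagged
    he <- make_scored_he(rep(c("1", "2"), each = 10),
                         rep(c("tumor", "macrophage"), each = 10),
                         rnorm(20), rnorm(20))
    cd <- SummarizedExperiment::colData(he)
    cd$pann <- rep(c(0.3, 0.3), each = 10)
    cd$knn_fraction <- rep(c(0.2, 0.2), each = 10)
    cd$density_ratio <- rep(c(1, 1), each = 10)
    SummarizedExperiment::colData(he) <- cd
    adj <- doubletAdjudication(adjudicateClusters(he))
    expect_false(any(adj$flagged_doublet))

    # a mid-pack cluster is not flagged; the top cluster in >= 2 methods is
    he2 <- make_scored_he(rep(c("1", "2", "3", "4", "5"), each = 10),
                          rep(c("tumor", "tumor", "tumor", "macrophage",
                                "other_immune"), each = 10),
                          rnorm(50), rnorm(50))
    cd <- SummarizedExperiment::colData(he2)
    cd$pann <- rep(c(0.1, 0.2, 0.9, 0.15, 0.05), each = 10)
    cd$knn_fraction <- rep(c(0.1, 0.2, 0.8, 0.15, 0.05), each = 10)
    cd$density_ratio <- rep(c(0.5, 1.0, 6.0, 0.8, 0.2), each = 10)
    SummarizedExperiment::colData(he2) <- cd
    adj2 <- doubletAdjudication(adjudicateClusters(he2))
    expect_identical(adj2$cluster[adj2$flagged_doublet], "3")
    expect_false(adj2$flagged_doublet[adj2$cluster == "2"])  # mid-pack
})

test_that("adjudication demotes a hybrid call on a flagged cluster", {
    set.seed(21)
    cluster <- rep(c("h", "t1", "t2", "t3", "m"), each = 20)
    cell_type <- rep(c("tumor", "tumor", "tumor", "tumor", "macrophage"),
                     each = 20)
    ts <- c(rnorm(20, 4), rnorm(60, 5), rnorm(20, 0))
    ms <- c(rnorm(20, 4), rnorm(60, 0), rnorm(20, 5))
    he <- make_scored_he(cluster, cell_type, ts, ms)
    he <- callHybridClusters(he)
    expect_identical(hybridClusterLabels(he), "h")
    cd <- SummarizedExperiment::colData(he)
    cd$pann <- ifelse(cluster == "h", 0.9, 0.05)
    cd$knn_fraction <- ifelse(cluster == "h", 0.9, 0.05)
    cd$density_ratio <- ifelse(cluster == "h", 5, 0.3)
    SummarizedExperiment::colData(he) <- cd
    he <- adjudicateClusters(he)
    calls <- hybridCalls(he)
    expect_length(hybridClusterLabels(he), 0)
    expect_true(calls$demoted[calls$cluster == "h"])
    expect_match(calls$reason[calls$cluster == "h"], "consensus")
})

test_that("single-cluster adjudication warns and does not flag", {
    he <- make_scored_he(rep("1", 10), rep("tumor", 10), rnorm(10),
                         rnorm(10))
    cd <- SummarizedExperiment::colData(he)
    cd$pann <- runif(10); cd$knn_fraction <- runif(10)
    cd$density_ratio <- runif(10)
    SummarizedExperiment::colData(he) <- cd
    expect_warning(he <- adjudicateClusters(he), "single cluster")
    expect_false(any(doubletAdjudication(he)$flagged_doublet))
})
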