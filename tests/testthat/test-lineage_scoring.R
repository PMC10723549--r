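test_that("marker ranking returns exactly n_top genes per lineage", {
    groups <- rep(c("tumor", "macrophage"), each = 30)
    up_a <- sprintf("G%03d", 1:120)   # 120 genes elevated in tumor
    mat <- make_group_counts(200, groups, elevated = list(tumor = up_a),
                             seed = 2)
    he <- logNormalize(make_he(mat, colData = data.frame(
        cell_type = groups, row.names = sprintf("C%03d", 1:60))))
    mk <- rankLineageMarkers(he, "tumor", "macrophage", n_top = 50)
    expect_length(mk$markers_a, 50)
    expect_true(all(mk$markers_a %in% up_a))
    expect_named(mk$de, c("gene", "log2fc", "p_value", "p_adjusted",
                          "pct_a", "pct_b"))
    expect_true(all(mk$de$p_adjusted >= mk$de$p_value))
})

test_that("a group-exclusive gene outranks a null gene", {
    groups <- rep(c("tumor", "macrophage"), each = 20)
    mat <- matrix(rpois(40 * 50, 2), nrow = 50,
                  dimnames = list(sprintf("G%03d", 1:50),
                                  sprintf("C%03d", 1:40)))
    mat["G001", ] <- c(rpois(20, 8), rep(0, 20))  # exclusive to tumor
    he <- logNormalize(make_he(mat, colData = data.frame(
        cell_type = groups, row.names = colnames(mat))))
    mk <- rankLineageMarkers(he, "tumor", "macrophage", n_top = 5)
    expect_equal(mk$markers_a[1], "G001")
    expect_error(rankLineageMarkers(he, "tumor", "absent"), "3 cells")
})

test_that("two-sided rank-sum p matches full enumeration on small groups", {
    mat <- matrix(0, nrow = 1, ncol = 6,
                  dimnames = list("G1", sprintf("C%d", 1:6)))
    mat[1, ] <- c(1, 2, 3, 4, 5, 6)
    he <- make_he(mat)
    SummarizedExperiment::assay(he, "logcounts") <-
        SummarizedExperiment::assay(he, "counts")
    de <- differentialExpression(he, 1:3, 4:6)
    expect_equal(de$p_value, 0.1)
    expect_equal(de$p_value, oracle_wilcox_p(c(1, 2, 3), c(4, 5, 6)))
})

test_that("module score matches the brute-force oracle on a toy matrix", {
    set.seed(99)
    mat <- matrix(rexp(60), nrow = 10,
                  dimnames = list(sprintf("g%02d", 1:10),
                                  sprintf("c%d", 1:6)))
    he <- make_he(matrix(1, 10, 6,
                         dimnames = dimnames(mat)))  # counts placeholder
    SummarizedExperiment::assay(he, "logcounts") <-
        Matrix::Matrix(mat, sparse = TRUE)
    gene_set <- c("g02", "g07", "g09")
    got <- moduleScore(he, gene_set, nbin = 2, n_ctrl = 1, seed = 0)
    want <- oracle_module_score(mat, gene_set, nbin = 2, n_ctrl = 1,
                                seed = 0)
    expect_lt(max(abs(got - want)), 1e-12)
})

test_that("module score degenerate cases and invariances", {
    mat <- matrix(3, nrow = 12, ncol = 5,
                  dimnames = list(sprintf("g%02d", 1:12),
                                  sprintf("c%d", 1:5)))
    he <- make_he(mat)
    SummarizedExperiment::assay(he, "logcounts") <- Matrix::Matrix(mat,
                                                                   sparse = TRUE)
    # constant matrix scores zero
    expect_equal(unname(moduleScore(he, c("g01", "g05"), nbin = 3)),
                 rep(0, 5))
    # gene_set = all genes with n_ctrl >= bin size scores zero
    set.seed(1)
    m2 <- matrix(rexp(60, 0.5), nrow = 12, dimnames = dimnames(mat))
    he2 <- he
    SummarizedExperiment::assay(he2, "logcounts") <- Matrix::Matrix(m2,
                                                                    sparse = TRUE)
    expect_equal(unname(moduleScore(he2, rownames(m2), nbin = 3,
                                    n_ctrl = 4)),
                 rep(0, 5), tolerance = 1e-12)
    # adding a constant to every entry leaves scores unchanged
    s1 <- moduleScore(he2, c("g01", "g08"), nbin = 3, n_ctrl = 2, seed = 5)
    he3 <- he2
    SummarizedExperiment::assay(he3, "logcounts") <-
        SummarizedExperiment::assay(he2, "logcounts") + 7
    s2 <- moduleScore(he3, c("g01", "g08"), nbin = 3, n_ctrl = 2, seed = 5)
    expect_equal(s1, s2, tolerance = 1e-12)
    # errors
    expect_error(moduleScore(he2, character()), "empty")
    expect_error(moduleScore(he2, "nope"), "absent")
    expect_error(moduleScore(he2, "g01", nbin = 50), "lower nbin")
})

test_that("lineage scores separate populations and expose hybrids", {
    he <- simulateCounts(simConfig(seed = 4))
    he <- logNormalize(qcFilter(he))
    mk <- rankLineageMarkers(he, "tumor", "macrophage")
    # planted tumor-program markers are recovered in the top-50 list
    planted <- lineageMarkerPanels(50)$tumor
    expect_gte(mean(planted %in% mk$markers_a), 0.9)
    he <- scoreLineages(he, mk$markers_a, mk$markers_b, seed = 4)
    tt <- truthTable(he)
    ts <- tumScore(he); ms <- macScore(he)
    tum <- tt$population == "tumor"; mac <- tt$population == "macrophage"
    hyb <- tt$population == "hybrid"
    expect_gt(mean(ts[tum]), mean(ts[mac]))
    expect_gt(mean(ms[mac]), mean(ms[tum]))
    # hybrids sit above the 75th percentile of the opposite lineage on both
    expect_gte(mean(ts[hyb] > quantile(ts[mac], 0.75)), 0.99)
    expect_gte(mean(ms[hyb] > quantile(ms[tum], 0.75)), 0.99)
})
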