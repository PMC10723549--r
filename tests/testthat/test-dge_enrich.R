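test_that("differential expression is well calibrated on null genes", {
    set.seed(31)
    mat <- matrix(rpois(200 * 120, 3), nrow = 200)
    he <- logNormalize(make_he(mat))
    de <- differentialExpression(he, 1:60, 61:120)
    expect_lt(median(abs(de$log2fc)), 0.2)
    expect_gt(mean(de$p_adjusted == 1), 0.95)   # Bonferroni over 200 genes
    expect_error(differentialExpression(he, 1:60, 50:120), "overlap")
    expect_error(differentialExpression(he, 1:2, 61:120), "3 cells")
})

test_that("single-gene exact p matches the enumeration oracle", {
    mat <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
                  dimnames = list("G1", sprintf("C%d", 1:6)))
    he <- make_he(mat)
    SummarizedExperiment::assay(he, "logcounts") <-
        SummarizedExperiment::assay(he, "counts")
    de <- differentialExpression(he, 1:3, 4:6)
    expect_equal(de$p_value, 0.1)
})

# helper to build a one-row DE table
de_row <- function(gene, lfc, p) data.frame(
    gene = gene, log2fc = lfc, p_value = p, p_adjusted = p,
    pct_a = rep(0.5, length(gene)), pct_b = rep(0.5, length(gene)),
    stringsAsFactors = FALSE)

test_that("panel selection applies the gene and pathway thresholds", {
    # |lfc| = 0.9 gene: below the gene-panel cut but above the pathway cut
    t1 <- de_row(c("A", "B"), c(0.9, 1.5), c(0.01, 0.01))
    s <- list(s1 = list(vs_tumor = t1, vs_mac = de_row("Z", 0, 1)),
              s2 = list(vs_tumor = t1, vs_mac = de_row("Z", 0, 1)))
    panel <- selectSharedPanel(s)
    expect_identical(panel$gene, "B")
    relaxed <- selectSharedPanel(s, lfc_gene = 0.58)
    expect_setequal(relaxed$gene, c("A", "B"))
})

test_that("sharing, top-k and downregulation-floor rules", {
    mk_tab <- function(genes, lfc) de_row(genes, lfc, 0.001)
    empty <- de_row(character(0), numeric(0), numeric(0))
    # gene significant in exactly 2 of 5 samples is retained
    samples <- lapply(1:5, function(i) list(
        vs_tumor = if (i <= 2) mk_tab("SHARED2", 2) else empty,
        vs_mac = empty))
    names(samples) <- paste0("p", 1:5)
    expect_identical(selectSharedPanel(samples)$gene, "SHARED2")
    samples1 <- samples
    samples1[[2]]$vs_tumor <- empty    # now only 1 of 5
    expect_equal(nrow(selectSharedPanel(samples1)), 0)

    # 30 shared upregulated genes collapse to the top 10 by adjusted p
    genes30 <- sprintf("U%02d", 1:30)
    tab30 <- de_row(genes30, 2, seq(1e-30, 1e-3, length.out = 30))
    s30 <- list(a = list(vs_tumor = tab30, vs_mac = empty),
                b = list(vs_tumor = tab30, vs_mac = empty))
    p30 <- selectSharedPanel(s30)
    expect_equal(nrow(p30), 10)
    expect_setequal(p30$gene, genes30[1:10])

    # hybrid-vs-mac downregulated genes must reach the -2.0 floor
    dn <- de_row(c("D1", "D2"), c(-1.2, -2.5), 0.001)
    sdn <- list(a = list(vs_tumor = empty, vs_mac = dn),
                b = list(vs_tumor = empty, vs_mac = dn))
    pdn <- selectSharedPanel(sdn)
    expect_identical(pdn$gene[pdn$category == "down_vs_mac"], "D2")

    # all-empty input gives an empty panel, and curated genes append
    expect_equal(nrow(selectSharedPanel(list(
        a = list(vs_tumor = empty, vs_mac = empty)))), 0)
    cur <- selectSharedPanel(samples, include = c("GPX1", "B2M"))
    expect_true(all(c("GPX1", "B2M") %in% cur$gene))
})

test_that("panel selection is monotone in the significance threshold", {
    set.seed(17)
    rand_tab <- function() de_row(sprintf("G%02d", 1:40),
                                  rnorm(40, 0, 2),
                                  runif(40, 0, 0.2))
    s <- list(a = list(vs_tumor = rand_tab(), vs_mac = rand_tab()),
              b = list(vs_tumor = rand_tab(), vs_mac = rand_tab()))
    strict <- selectSharedPanel(s, alpha_adj = 0.01, top_k_up_vs_tumor = 100)
    loose <- selectSharedPanel(s, alpha_adj = 0.10, top_k_up_vs_tumor = 100)
    key <- function(p) paste(p$gene, p$category)
    expect_true(all(key(strict) %in% key(loose)))
})

test_that("hypergeometric ORA matches exact enumeration", {
    sets <- list(S = sprintf("G%02d", 1:5),
                 disjoint = c("X1", "X2"))
    universe <- sprintf("G%02d", 1:10)
    res <- overrepresentation(sprintf("G%02d", 1:5), universe, sets)
    expect_equal(res$p_value[res$set_name == "S"], 1 / 252)
    expect_equal(res$p_value[res$set_name == "S"],
                 oracle_hyper_p(10, 5, 5, 5))
    expect_equal(res$set_size_K[res$set_name == "disjoint"], 0)
    expect_equal(res$p_value[res$set_name == "disjoint"], 1)
    # zero overlap has upper-tail p = 1
    res0 <- overrepresentation(c("G06", "G07"), universe,
                               list(S = sprintf("G%02d", 1:5)))
    expect_equal(res0$p_value, 1)
    # random small universes against the enumeration oracle
    set.seed(23)
    for (i in 1:10) {
        M <- sample(6:12, 1)
        K <- sample(1:(M - 1), 1)
        n <- sample(1:(M - 1), 1)
        uni <- sprintf("u%02d", 1:M)
        hits <- sample(uni, n)
        res <- overrepresentation(hits, uni, list(S = uni[1:K]))
        k <- res$overlap_k
        expect_equal(res$p_value, oracle_hyper_p(M, K, n, k),
                     tolerance = 1e-12)
    }
    expect_error(overrepresentation("a", character(), list()), "universe")
    expect_error(overrepresentation("a", "b", list()), "subset")
})

test_that("planted hybrid-elevated genes are recovered versus tumor", {
    he <- simulateCounts(simConfig(populations = c(tumor = 250,
                                                   macrophage = 150),
                                   hybrid_fraction = 0.1, seed = 14))
    he <- logNormalize(qcFilter(he))
    tt <- truthTable(he)
    de <- differentialExpression(he, which(tt$population == "hybrid"),
                                 which(tt$population == "tumor"))
    up <- de$gene[de$p_adjusted <= 0.05 & de$log2fc >= 1]
    planted <- lineageMarkerPanels(50)$macrophage
    expect_gte(mean(planted %in% up), 0.8)
})

test_that("bundled GMT reader returns named gene sets", {
    gmt <- readGmt(system.file("extdata", "hallmark_mini.gmt",
                               package = "scHybrid"))
    expect_true("MELANOCYTE_PROGRAM" %in% names(gmt))
    expect_true("MITF" %in% gmt$MELANOCYTE_PROGRAM)
})
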