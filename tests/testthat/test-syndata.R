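# shared default-condition simulation (singlets only; doublets spiked where
# a test needs them)
he_def <- simulateCounts(simConfig(seed = 1))

test_that("hybrid_fraction = 0 yields no hybrid cells", {
    cfg <- simConfig(populations = c(tumor = 300, macrophage = 200),
                     hybrid_fraction = 0, n_genes = 400, seed = 3)
    he <- simulateCounts(cfg)
    expect_equal(ncol(he), 500)
    expect_false("hybrid" %in% truthTable(he)$population)
})

test_that("simulation is bit-reproducible for a fixed seed", {
    cfg <- simConfig(populations = c(tumor = 80, macrophage = 60),
                     n_genes = 400, seed = 7)
    a <- simulateCounts(cfg)
    b <- simulateCounts(cfg)
    expect_identical(as.matrix(counts(a)), as.matrix(counts(b)))
    expect_identical(truthTable(a), truthTable(b))
})

test_that("hybrids are generated at singlet library depth", {
    tt <- truthTable(he_def)
    lib <- Matrix::colSums(counts(he_def))
    hyb <- lib[tt$population == "hybrid"]
    tum <- lib[tt$population == "tumor"]
    se <- sqrt(var(hyb) / length(hyb) + var(tum) / length(tum))
    expect_lt(abs(mean(hyb) - mean(tum)), 2 * se)
})

test_that("planted marker structure separates the lineage programs", {
    tt <- truthTable(he_def)
    panels <- lineageMarkerPanels(50)
    m <- counts(he_def)
    tum_mean <- Matrix::rowMeans(m[, tt$population == "tumor"])
    mac_mean <- Matrix::rowMeans(m[, tt$population == "macrophage"])
    expect_true(all(tum_mean[panels$tumor] > mac_mean[panels$tumor]))
    expect_true(all(mac_mean[panels$macrophage] >
                        tum_mean[panels$macrophage]))
})

test_that("spiked doublets are exact parent sums at the requested rate", {
    cfg <- simConfig(populations = c(tumor = 150, macrophage = 100),
                     hybrid_fraction = 0, n_genes = 400, seed = 5)
    he <- simulateCounts(cfg)
    out <- spikeDoublets(he, rate = 0.1, seed = 11)
    tt <- truthTable(out)
    dbl <- tt[tt$population == "doublet", ]
    expect_equal(nrow(dbl), 25)  # round(0.1 * 250)
    m <- counts(out)
    for (i in seq_len(nrow(dbl)))
        expect_equal(m[, dbl$barcode[i]],
                     m[, dbl$parent_1[i]] + m[, dbl$parent_2[i]])
    expect_true(all(dbl$parent_1 != dbl$parent_2))
    # rate 0 is a no-op
    expect_identical(spikeDoublets(he, rate = 0), he)
})

test_that("doublet library sizes separate from singlet library sizes", {
    he <- spikeDoublets(he_def, seed = 2)
    tt <- truthTable(he)
    lib <- Matrix::colSums(counts(he))
    expect_gt(median(lib[tt$population == "doublet"]),
              1.5 * median(lib[tt$population != "doublet"]))
})

test_that("config validation rejects inconsistent parameters", {
    expect_error(simConfig(hybrid_fraction = 0.5, doublet_rate = 0.6),
                 "must be < 1")
    expect_error(simConfig(hybrid_mixture_range = c(0.7, 0.3)), "interval")
    expect_error(simConfig(populations = c(tumor = 100)), "macrophage")
    expect_error(simConfig(library_size_mean = -5), "library_size_mean")
    expect_error(spikeDoublets(simulateCounts(
        simConfig(populations = c(tumor = 50, macrophage = 50),
                  n_genes = 400)), rate = 1), "< 1")
})

test_that("intensity simulator emulates the cyCIF panel with truth labels", {
    sim <- simulateIntensities(
        intensitySimConfig(populations = c(hybrid = 100, tumor = 50),
                           seed = 3))
    expect_equal(nrow(sim$intensities), 150)
    expect_true(all(c("CD45", "MITF", "TYR", "MLANA", "GP100", "HTR2B",
                      "CD25", "CD203c", "TMSB10", "CD74", "GPX1") %in%
                        colnames(sim$intensities)))
    vals <- sim$intensities[, intensitySimConfig()$markers]
    expect_true(all(vals > 0))
    expect_identical(sim$truth$population,
                     rep(c("hybrid", "tumor"), c(100, 50)))
    expect_error(simulateIntensities(intensitySimConfig(markers = character())),
                 "empty")
})

test_that("hybrid and leukocyte CD45 intensities share a distribution under equal meanlogs", {
    cfg <- intensitySimConfig(populations = c(hybrid = 2000,
                                              leukocyte = 2000), seed = 9)
    # default config already sets hybrid CD45 meanlog equal to leukocyte's
    expect_equal(cfg$meanlog["CD45", "hybrid"],
                 cfg$meanlog["CD45", "leukocyte"])
    sim <- simulateIntensities(cfg)
    x <- sim$intensities$CD45[sim$truth$population == "hybrid"]
    y <- sim$intensities$CD45[sim$truth$population == "leukocyte"]
    se <- sqrt(var(x) / length(x) + var(y) / length(y))
    expect_lt(abs(mean(x) - mean(y)), 3 * se)
})
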