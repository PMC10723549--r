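#' Lineage marker panels used by the synthetic generator
#'
#' Returns the gene symbols planted as lineage-program markers. The leading
#' symbols of each program are canonical markers of the corresponding cell
#' type in uveal melanoma tumors (melanocytic program: MITF, MLANA, DCT, TYR,
#' GP100, HTR2B; macrophage/monocyte program: PTPRC (CD45), CD14, CD163, ...),
#' padded with synthetic placeholder symbols (`TUM###`, `MAC###`, ...) up to
#' the requested program size. Ligand and receptor genes of well-known
#' tumor-macrophage signaling axes (GAS6-AXL, CXCL12-CXCR4, LGALS9-P4HB,
#' IGF1-IGF1R, TYROBP-CD44, APP-CD74, ANXA1-FPR1/FPR3) are embedded in the
#' appropriate programs so ligand-receptor inference is exercisable on
#' synthetic data.
#'
#' @param n_marker_genes markers per lineage program.
#' @return named list of character vectors
#'   (`tumor`, `macrophage`, `tcell`, `stromal`).
#' @export
lineageMarkerPanels <- function(n_marker_genes = 50) {
    .assert_scalar_num(n_marker_genes, "n_marker_genes", 1, integer = TRUE)
    named <- list(
        tumor = c("MITF", "MLANA", "DCT", "TYR", "GP100", "HTR2B",
                  "CD44", "AXL", "P4HB", "IGF1R", "APP", "PRAME"),
        macrophage = c("PTPRC", "CD14", "CD163", "CD68", "AIF1", "TYROBP",
                       "CD74", "GAS6", "LGALS9", "ANXA1", "IGF1", "CXCL12",
                       "TMSB10", "GPX1", "SEPP1", "B2M", "FPR1", "FPR3",
                       "RHOA", "S100A11"),
        tcell = c("CD3D", "CD3E", "CD2", "IL7R", "CXCR4", "IL2RA"),
        stromal = c("COL1A1", "COL3A1", "ACTA2", "PECAM1", "VWF", "DCN"))
    pad <- c(tumor = "TUM", macrophage = "MAC", tcell = "TCL",
             stromal = "STR")
    lapply(stats::setNames(names(named), names(named)), function(p) {
        g <- named[[p]]
        if (length(g) >= n_marker_genes) return(g[seq_len(n_marker_genes)])
        c(g, sprintf("%s%03d", pad[[p]],
                     seq_len(n_marker_genes - length(g))))
    })
}

#' Configuration of the synthetic scRNA-seq generator
#'
#' Defines the study conditions the generator emulates: a droplet scRNA-seq
#' sample from a primary uveal melanoma containing tumor cells, macrophages/
#' monocytes, other immune (T) cells, stromal cells, a rare hybrid population
#' co-expressing the tumor and macrophage programs *at singlet library
#' depth*, and (spiked separately, see [spikeDoublets()]) artifactual
#' doublets formed by summing two cells' libraries.
#'
#' Each cell draws a library size from a lognormal distribution; its expected
#' gene proportions follow its population's expression program (a shared
#' lognormal gene baseline with that program's marker genes elevated
#' `marker_fold`-fold); observed counts are negative binomial around
#' `library_size * proportion` with dispersion `nb_dispersion`. A hybrid cell
#' draws a mixing weight `lambda ~ Uniform(hybrid_mixture_range)` and uses
#' the proportion vector `lambda * tumor + (1 - lambda) * macrophage` — at a
#' singlet library size, which is the property that distinguishes hybrids
#' from doublets.
#'
#' @param n_genes number of genes.
#' @param populations named integer vector of singlet (non-hybrid) population
#'   sizes; names must be a subset of
#'   `c("tumor", "macrophage", "tcell", "stromal")` and must include `tumor`
#'   and `macrophage`.
#' @param n_marker_genes markers per lineage program (the top-marker analyses
#'   use 50).
#' @param marker_fold fold elevation of a program's markers over baseline.
#' @param hybrid_fraction fraction of all singlets that are hybrid cells.
#' @param hybrid_mixture_range interval `c(lo, hi)` in (0,1) for the hybrid
#'   tumor-program weight lambda.
#' @param doublet_rate default doublet spike-in rate used by pipelines
#'   calling [spikeDoublets()].
#' @param library_size_mean,library_size_dispersion mean and lognormal sdlog
#'   of the per-cell library size.
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param sample_id sample identifier for barcodes and annotations.
#' @param seed integer RNG seed.
#'
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(n_genes = 2000,
                      populations = c(tumor = 900, macrophage = 500,
                                      tcell = 300, stromal = 200),
                      n_marker_genes = 50,
                      marker_fold = 10,
                      hybrid_fraction = 0.05,
                      hybrid_mixture_range = c(0.3, 0.7),
                      doublet_rate = 0.10,
                      library_size_mean = 2000,
                      library_size_dispersion = 0.35,
                      nb_dispersion = 0.1,
                      sample_id = "SYN1",
                      seed = 1) {
    .assert_scalar_num(n_genes, "n_genes", 1, integer = TRUE)
    if (is.null(names(populations)) || any(populations <= 0) ||
        any(populations != round(populations)))
        stop("'populations' must be a named vector of positive counts")
    if (!all(c("tumor", "macrophage") %in% names(populations)))
        stop("'populations' must include 'tumor' and 'macrophage'")
    if (!all(names(populations) %in%
             c("tumor", "macrophage", "tcell", "stromal")))
        stop("unknown population name")
    .assert_scalar_num(n_marker_genes, "n_marker_genes", 1, integer = TRUE)
    .assert_scalar_num(marker_fold, "marker_fold", lower = 1)
    .assert_scalar_num(hybrid_fraction, "hybrid_fraction", 0, 1)
    .assert_scalar_num(doublet_rate, "doublet_rate", 0, 1)
    if (hybrid_fraction + doublet_rate >= 1)
        stop("hybrid_fraction + doublet_rate must be < 1")
    if (length(hybrid_mixture_range) != 2L ||
        hybrid_mixture_range[1] >= hybrid_mixture_range[2] ||
        hybrid_mixture_range[1] <= 0 || hybrid_mixture_range[2] >= 1)
        stop("'hybrid_mixture_range' must be an interval (lo, hi) in (0,1)")
    .assert_scalar_num(library_size_mean, "library_size_mean", lower = 1)
    .assert_scalar_num(library_size_dispersion, "library_size_dispersion",
                       lower = 1e-8)
    .assert_scalar_num(nb_dispersion, "nb_dispersion", lower = 1e-8)
    .assert_scalar_num(seed, "seed", integer = TRUE)
    if (4 * n_marker_genes > n_genes)
        stop("n_genes too small for four marker programs")
    structure(list(
        n_genes = as.integer(n_genes),
        populations = populations,
        n_marker_genes = as.integer(n_marker_genes),
        marker_fold = marker_fold,
        hybrid_fraction = hybrid_fraction,
        hybrid_mixture_range = hybrid_mixture_range,
        doublet_rate = doublet_rate,
        library_size_mean = library_size_mean,
        library_size_dispersion = library_size_dispersion,
        nb_dispersion = nb_dispersion,
        sample_id = sample_id,
        seed = as.integer(seed)), class = "SimConfig")
}

# population -> source-style cell-type annotation. Hybrids carry a tumor
# annotation (a source atlas has no hybrid category); doublets are annotated
# by their expression-dominant parent in spikeDoublets().
.annotation_map <- c(tumor = "tumor", macrophage = "macrophage",
                     tcell = "other_immune", stromal = "stromal",
                     hybrid = "tumor")

#' Simulate a synthetic droplet scRNA-seq sample with hybrid-cell truth
#'
#' Draws singlet cells (including the rare hybrid population) under the model
#' described in [simConfig()]. Doublets are added separately with
#' [spikeDoublets()] so tests can target either layer.
#'
#' @param config a [simConfig()] object.
#' @return a [HybridExperiment-class] whose `colData` holds the ground truth
#'   (`population`, `mixture_lambda`) and the source-style `cell_type`
#'   annotation used by downstream stages. The config is kept in
#'   `metadata(x)$sim_config`.
#'
#' @examples
#' he <- simulateCounts(simConfig(populations = c(tumor = 60, macrophage = 40),
#'                                n_genes = 400, seed = 7))
#' table(truthTable(he)$population)
#' @export
simulateCounts <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    .with_seed(config$seed, {
        panels <- lineageMarkerPanels(config$n_marker_genes)
        marker_syms <- unlist(panels, use.names = FALSE)
        n_other <- config$n_genes - length(marker_syms)
        genes <- c(marker_syms, sprintf("GENE%04d", seq_len(n_other)))

        # shared lognormal baseline; program markers elevated marker_fold-x
        base_w <- stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 1)
        names(base_w) <- genes
        programs <- list()
        for (p in names(panels)) {
            w <- base_w
            w[panels[[p]]] <- w[panels[[p]]] * config$marker_fold
            programs[[p]] <- w / sum(w)
        }

        pops <- config$populations
        n_singlet_nonhyb <- sum(pops)
        n_hybrid <- round(config$hybrid_fraction /
                          (1 - config$hybrid_fraction) * n_singlet_nonhyb)
        pop_lab <- c(rep(names(pops), times = pops),
                     rep("hybrid", n_hybrid))
        n_cells <- length(pop_lab)

        lambda <- rep(NA_real_, n_cells)
        if (n_hybrid > 0)
            lambda[pop_lab == "hybrid"] <- stats::runif(
                n_hybrid, config$hybrid_mixture_range[1],
                config$hybrid_mixture_range[2])

        sdl <- config$library_size_dispersion
        lib <- stats::rlnorm(n_cells,
                             meanlog = log(config$library_size_mean) -
                                 sdl^2 / 2,
                             sdlog = sdl)

        size <- 1 / config$nb_dispersion
        counts <- matrix(0L, nrow = config$n_genes, ncol = n_cells)
        for (i in seq_len(n_cells)) {
            pr <- if (pop_lab[i] == "hybrid")
                lambda[i] * programs$tumor +
                    (1 - lambda[i]) * programs$macrophage
            else programs[[pop_lab[i]]]
            counts[, i] <- stats::rnbinom(config$n_genes,
                                          mu = lib[i] * pr, size = size)
        }
        barcodes <- sprintf("%s_C%05d", config$sample_id, seq_len(n_cells))
        dimnames(counts) <- list(genes, barcodes)

        cd <- S4Vectors::DataFrame(
            population = pop_lab,
            cell_type = unname(.annotation_map[pop_lab]),
            sample_id = config$sample_id,
            mixture_lambda = lambda,
            parent_1 = NA_character_,
            parent_2 = NA_character_,
            row.names = barcodes)
        he <- HybridExperiment(Matrix::Matrix(counts, sparse = TRUE),
                               colData = cd)
        S4Vectors::metadata(he)$sim_config <- config
        he
    })
}

#' Spike artifactual doublets into a synthetic sample
#'
#' Appends `round(rate * n_singlets)` doublet columns, each the element-wise
#' sum of two distinct, randomly chosen singlet libraries — the generative
#' definition of a droplet doublet. Parent barcodes are recorded in the
#' truth table; the doublet's `cell_type` annotation is inherited from the
#' parent with the larger library (the parent that dominates its expression,
#' as a reference-based annotation would see it).
#'
#' @param he a [HybridExperiment-class] from [simulateCounts()].
#' @param rate doublet rate in `[0, 1)`, relative to the number of singlets.
#'   Defaults to the generating config's `doublet_rate`.
#' @param seed RNG seed (default: config seed + 1).
#' @return the input with doublet columns appended.
#' @export
spikeDoublets <- function(he, rate = NULL, seed = NULL) {
    stopifnot(methods::is(he, "HybridExperiment"))
    cfg <- S4Vectors::metadata(he)$sim_config
    if (is.null(rate)) rate <- cfg$doublet_rate
    if (is.null(rate)) stop("'rate' required when no sim_config is present")
    .assert_scalar_num(rate, "rate", 0)
    if (rate >= 1) stop("'rate' must be < 1")
    if (is.null(seed)) seed <- if (!is.null(cfg)) cfg$seed + 1L else 0L
    if (rate == 0) return(he)

    cd <- SummarizedExperiment::colData(he)
    singlet <- which(is.na(cd$parent_1))
    if (length(singlet) < 2L) stop("need at least 2 singlets to form doublets")
    n_dbl <- round(rate * length(singlet))
    if (n_dbl == 0L) return(he)

    .with_seed(seed, {
        p1 <- sample(singlet, n_dbl, replace = TRUE)
        p2 <- vapply(p1, function(i)
            sample(singlet[singlet != i], 1L), integer(1))
        cts <- .counts(he)
        dbl <- cts[, p1, drop = FALSE] + cts[, p2, drop = FALSE]
        sample_id <- if (!is.null(cd$sample_id)) cd$sample_id[1] else "S"
        colnames(dbl) <- sprintf("%s_D%05d", sample_id, seq_len(n_dbl))

        lib <- Matrix::colSums(cts)
        dominant <- ifelse(lib[p1] >= lib[p2], p1, p2)
        cd_dbl <- S4Vectors::DataFrame(
            population = "doublet",
            cell_type = cd$cell_type[dominant],
            sample_id = sample_id,
            mixture_lambda = NA_real_,
            parent_1 = colnames(he)[p1],
            parent_2 = colnames(he)[p2],
            row.names = colnames(dbl))

        out <- HybridExperiment(cbind(cts, dbl),
                                colData = rbind(cd, cd_dbl))
        S4Vectors::metadata(out) <- S4Vectors::metadata(he)
        out
    })
}
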