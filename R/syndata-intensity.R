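.default_cycif_markers <- c("CD45", "MITF", "TYR", "MLANA", "GP100", "HTR2B",
                            "CD25", "CD203c", "TMSB10", "CD74", "GPX1")

.default_intensity_meanlog <- function(markers, compartment) {
    pops <- c("hybrid", "tumor", "leukocyte", "basophil_like", "treg_like")
    bg <- log(50); hi <- log(500); mid <- log(300)
    m <- matrix(bg, nrow = length(markers), ncol = length(pops),
                dimnames = list(markers, pops))
    melano <- intersect(c("MITF", "TYR", "MLANA", "GP100", "HTR2B"), markers)
    m[melano, "tumor"] <- hi
    m[melano, "hybrid"] <- mid
    m["CD45", c("hybrid", "leukocyte", "basophil_like", "treg_like")] <- hi
    if ("HTR2B" %in% markers)
        m["HTR2B", c("basophil_like", "treg_like")] <- mid
    if ("CD203c" %in% markers) m["CD203c", "basophil_like"] <- hi
    if ("CD25" %in% markers) m["CD25", "treg_like"] <- hi
    # phenotype markers: in tumor tissue hybrid and tumor cells express them
    # at similar levels; in peripheral blood disseminated hybrids (CHCs) have
    # elevated TMSB10/GPX1 relative to CTCs and higher CD74 than tumor-
    # resident hybrids
    pheno <- intersect(c("TMSB10", "CD74", "GPX1"), markers)
    if (compartment == "tumor_tissue") {
        m[pheno, c("hybrid", "tumor")] <- log(200)
    } else {
        m[intersect(c("TMSB10", "GPX1"), markers), "hybrid"] <- log(450)
        m[pheno, "tumor"] <- log(120)
        if ("CD74" %in% markers) {
            m["CD74", "hybrid"] <- log(300)
            m["CD74", "tumor"] <- log(250)
        }
    }
    m
}

#' Configuration of the synthetic cyCIF intensity generator
#'
#' Emulates per-cell mean fluorescent intensity tables from cyclic
#' immunofluorescence of uveal melanoma: a tumor-tissue section or a
#' peripheral-blood (PBMC) slide containing hybrid cells, tumor cells (CTCs
#' in blood), ordinary leukocytes, and the two confuser populations the
#' gating rules must exclude (basophil-like: CD45+/HTR2B+/CD203c+;
#' Treg-like: CD45+/HTR2B+/CD25+). Intensities are lognormal per marker per
#' population.
#'
#' The default marker panel is the melanocytic/immune antibody panel
#' (MITF, TYR, MLANA, GP100, HTR2B; CD45, CD25, CD203c) plus the three
#' phenotype markers TMSB10, CD74 and GPX1.
#'
#' @param markers character vector of marker names.
#' @param populations named sizes for
#'   `hybrid, tumor, leukocyte, basophil_like, treg_like` (any subset).
#' @param meanlog optional markers x populations matrix of lognormal
#'   meanlogs; a compartment-appropriate default is built when `NULL`.
#' @param sdlog lognormal sdlog (scalar or per-marker vector).
#' @param compartment `"tumor_tissue"` or `"peripheral_blood"`; switches the
#'   default phenotype-marker means (blood hybrids have elevated
#'   TMSB10/GPX1).
#' @param sample_id sample identifier.
#' @param seed integer RNG seed.
#' @return a list of class `IntensitySimConfig`.
#' @export
intensitySimConfig <- function(markers = .default_cycif_markers,
                               populations = c(hybrid = 80, tumor = 300,
                                               leukocyte = 500,
                                               basophil_like = 30,
                                               treg_like = 30),
                               meanlog = NULL,
                               sdlog = 0.4,
                               compartment = c("tumor_tissue",
                                               "peripheral_blood"),
                               sample_id = "CY1",
                               seed = 1) {
    compartment <- match.arg(compartment)
    if (length(markers) == 0) stop("empty marker list")
    if (is.null(names(populations)) || any(populations <= 0))
        stop("'populations' must be named positive sizes")
    if (is.null(meanlog))
        meanlog <- .default_intensity_meanlog(markers, compartment)
    meanlog <- meanlog[markers, names(populations), drop = FALSE]
    if (any(sdlog <= 0)) stop("'sdlog' must be positive")
    .assert_scalar_num(seed, "seed", integer = TRUE)
    structure(list(markers = markers,
                   populations = populations,
                   meanlog = meanlog,
                   sdlog = rep_len(sdlog, length(markers)),
                   compartment = compartment,
                   sample_id = sample_id,
                   seed = as.integer(seed)),
              class = "IntensitySimConfig")
}

#' Simulate a cyCIF per-cell intensity table with population truth
#'
#' @param config an [intensitySimConfig()] object.
#' @return list with `intensities` (`data.frame`: `cell_id`, `sample_id`,
#'   `compartment`, one positive column per marker) and `truth`
#'   (`data.frame`: `cell_id`, `population`).
#' @examples
#' sim <- simulateIntensities(
#'   intensitySimConfig(populations = c(hybrid = 100, tumor = 50), seed = 3))
#' nrow(sim$intensities)  # 150
#' @export
simulateIntensities <- function(config) {
    stopifnot(inherits(config, "IntensitySimConfig"))
    .with_seed(config$seed, {
        pop_lab <- rep(names(config$populations),
                       times = config$populations)
        n <- length(pop_lab)
        cell_id <- sprintf("%s_cell%05d", config$sample_id, seq_len(n))
        vals <- vapply(seq_along(config$markers), function(j) {
            stats::rlnorm(n,
                          meanlog = config$meanlog[j, pop_lab],
                          sdlog = config$sdlog[j])
        }, numeric(n))
        colnames(vals) <- config$markers
        intensities <- cbind(
            data.frame(cell_id = cell_id,
                       sample_id = config$sample_id,
                       compartment = config$compartment,
                       stringsAsFactors = FALSE),
            as.data.frame(vals))
        list(intensities = intensities,
             truth = data.frame(cell_id = cell_id, population = pop_lab,
                                stringsAsFactors = FALSE))
    })
}
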