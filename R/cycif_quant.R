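#' Gating configuration for cyCIF intensity tables
#'
#' Marker roles and per-marker positivity thresholds for identifying hybrid
#' and tumor cells from per-cell mean fluorescent intensities. A cell is
#' positive for a marker when its intensity is greater than or *equal to*
#' the marker's minimum intensity value (inclusive threshold). Thresholds
#' play the role of the per-sample minimum intensity values recorded from
#' negative staining controls; [thresholdFromControls()] derives them from
#' a negative-control table.
#'
#' @param melanocyte_markers melanocytic tumor markers
#'   (default MITF, TYR, MLANA, GP100, HTR2B).
#' @param leukocyte_marker pan-leukocyte marker (default CD45).
#' @param exclusion_markers markers excluding basophil/Treg confusers
#'   (default CD25, CD203c).
#' @param phenotype_markers phenotype markers quantified per class
#'   (default TMSB10, CD74, GPX1).
#' @param thresholds named positive numeric vector of minimum intensity
#'   values, one per marker used (a scalar is recycled to all markers).
#' @param strict_htr2b_exclusion if `TRUE` (default) only cells whose sole
#'   melanocyte positivity is HTR2B are excluded when CD25/CD203c-positive;
#'   if `FALSE`, any CD45+/HTR2B+/CD25+ or CD203c+ cell is excluded.
#' @return a list of class `GateConfig`.
#' @export
gateConfig <- function(melanocyte_markers = c("MITF", "TYR", "MLANA",
                                              "GP100", "HTR2B"),
                       leukocyte_marker = "CD45",
                       exclusion_markers = c("CD25", "CD203c"),
                       phenotype_markers = c("TMSB10", "CD74", "GPX1"),
                       thresholds = 150,
                       strict_htr2b_exclusion = TRUE) {
    markers <- c(melanocyte_markers, leukocyte_marker, exclusion_markers,
                 phenotype_markers)
    if (anyDuplicated(c(melanocyte_markers, leukocyte_marker,
                        exclusion_markers)))
        stop("melanocyte, leukocyte and exclusion marker sets must be ",
             "disjoint")
    if (is.null(names(thresholds))) {
        if (length(thresholds) != 1)
            stop("'thresholds' must be named or a single value")
        thresholds <- stats::setNames(rep(thresholds, length(markers)),
                                      markers)
    }
    if (!all(markers %in% names(thresholds)))
        stop("missing thresholds for: ",
             paste(setdiff(markers, names(thresholds)), collapse = ", "))
    if (any(thresholds <= 0)) stop("thresholds must be positive")
    structure(list(melanocyte_markers = melanocyte_markers,
                   leukocyte_marker = leukocyte_marker,
                   exclusion_markers = exclusion_markers,
                   phenotype_markers = phenotype_markers,
                   thresholds = thresholds[markers],
                   strict_htr2b_exclusion = strict_htr2b_exclusion),
              class = "GateConfig")
}

#' Derive gating thresholds from a negative-control table
#'
#' @param controls `data.frame` of negative-control cell intensities (one
#'   column per marker).
#' @param markers marker columns to use.
#' @param quantile control quantile taken as the minimum intensity value
#'   (default 1, i.e. the control maximum).
#' @return named threshold vector usable in [gateConfig()].
#' @export
thresholdFromControls <- function(controls, markers, quantile = 1) {
    vapply(stats::setNames(markers, markers), function(m) {
        if (!m %in% colnames(controls)) stop("missing marker column: ", m)
        as.numeric(stats::quantile(controls[[m]], quantile))
    }, numeric(1))
}

#' Gate cells into hybrid / tumor / excluded / other classes
#'
#' Classification of per-cell mean intensities:
#' * **hybrid** — CD45-positive with one or more melanocyte markers
#'   positive, *except* cells whose only melanocyte positivity is HTR2B and
#'   which are also CD25- or CD203c-positive; those are **excluded** (they
#'   cannot be distinguished from basophils or regulatory T cells);
#' * **tumor** — one or more melanocyte markers positive with CD45, CD25
#'   and CD203c all below threshold;
#' * **other** — everything else.
#' Positivity is inclusive (`intensity >= threshold`).
#'
#' @param intensities `data.frame` with a `cell_id` column and one column
#'   per marker.
#' @param config a [gateConfig()].
#' @return `data.frame` with `cell_id`, `class`, and one logical
#'   `pos_<marker>` column per phenotype marker.
#' @export
gateCells <- function(intensities, config = gateConfig()) {
    stopifnot(inherits(config, "GateConfig"))
    needed <- names(config$thresholds)
    missing <- setdiff(needed, colnames(intensities))
    if (length(missing) > 0)
        stop("missing marker column(s): ", paste(missing, collapse = ", "))
    pos <- vapply(needed, function(m)
        intensities[[m]] >= config$thresholds[[m]],
        logical(nrow(intensities)))
    pos <- matrix(pos, nrow = nrow(intensities),
                  dimnames = list(NULL, needed))

    mel_pos <- pos[, config$melanocyte_markers, drop = FALSE]
    n_mel <- rowSums(mel_pos)
    cd45 <- pos[, config$leukocyte_marker]
    excl_any <- rowSums(pos[, config$exclusion_markers,
                            drop = FALSE]) > 0

    only_htr2b <- if ("HTR2B" %in% config$melanocyte_markers)
        mel_pos[, "HTR2B"] & n_mel == 1 else rep(FALSE, nrow(pos))
    confuser <- if (config$strict_htr2b_exclusion)
        cd45 & only_htr2b & excl_any
    else if ("HTR2B" %in% config$melanocyte_markers)
        cd45 & pos[, "HTR2B"] & excl_any
    else rep(FALSE, nrow(pos))

    class <- rep("other", nrow(pos))
    class[cd45 & n_mel >= 1] <- "hybrid"
    class[!cd45 & !excl_any & n_mel >= 1] <- "tumor"
    class[confuser] <- "excluded"

    out <- data.frame(cell_id = intensities$cell_id, class = class,
                      stringsAsFactors = FALSE)
    for (m in config$phenotype_markers)
        out[[paste0("pos_", m)]] <- pos[, m]
    out
}

#' Percent of a gated class positive for a phenotype marker
#'
#' `100 * (positive cells of the class) / (total cells of the class)`.
#' Errors (rather than returning 0) when the class has no cells, since the
#' percentage is undefined.
#'
#' @param gates output of [gateCells()].
#' @param cell_class `"hybrid"` or `"tumor"` (any gated class).
#' @param marker phenotype marker name.
#' @return percentage in `[0, 100]`.
#' @export
percentPositive <- function(gates, cell_class, marker) {
    col <- paste0("pos_", marker)
    if (!col %in% colnames(gates)) stop("marker not gated: ", marker)
    sel <- gates$class == cell_class
    if (!any(sel)) stop("no cells of class '", cell_class,
                        "'; percentage undefined")
    100 * sum(gates[[col]][sel]) / sum(sel)
}

#' Welch's two-sample t-test on percent-positive values
#'
#' Two-sided Welch (unequal-variance) t-test comparing per-sample
#' percent-positive values between two arms (e.g. hybrid cells vs tumor
#' cells across patients): `t = (mean_a - mean_b) /
#' sqrt(s2_a/n_a + s2_b/n_b)` with Welch-Satterthwaite degrees of freedom.
#'
#' @param values_a,values_b numeric vectors (each of length >= 2 with
#'   nonzero pooled variance).
#' @return list with `t_statistic`, `df`, `p_value`.
#' @export
compareGroups <- function(values_a, values_b) {
    if (length(values_a) < 2 || length(values_b) < 2)
        stop("each group needs at least 2 values")
    if (stats::var(values_a) == 0 && stats::var(values_b) == 0)
        stop("both groups have zero variance")
    tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
    list(t_statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value)
}
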