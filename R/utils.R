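# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old))
                rm(".Random.seed", envir = globalenv())
            else
                assign(".Random.seed", old, envir = globalenv())
        }, add = TRUE)
        set.seed(seed)
    }
    expr
}

.assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                               integer = FALSE) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
        stop("'", name, "' must be a single finite number")
    if (x < lower || x > upper)
        stop("'", name, "' must be in [", lower, ", ", upper, "]")
    if (integer && x != round(x))
        stop("'", name, "' must be an integer")
    invisible(x)
}

.counts <- function(x) SummarizedExperiment::assay(x, "counts")

.logcounts <- function(x) {
    if (!"logcounts" %in% SummarizedExperiment::assayNames(x))
        stop("no 'logcounts' assay; run logNormalize() first")
    SummarizedExperiment::assay(x, "logcounts")
}
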