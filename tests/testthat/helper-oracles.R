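# Independent oracles used to validate the package's statistics. Each is a
# deliberately naive implementation (enumeration / closed form / brute
# force), sharing no code with the package internals.

# exact rank-sum p-value by full enumeration of all C(n1+n2, n1) group
# assignments (no ties assumed)
oracle_wilcox_p <- function(x, y, alternative = c("two.sided", "greater")) {
    alternative <- match.arg(alternative)
    v <- c(x, y)
    n1 <- length(x)
    rk <- rank(v)
    obs <- sum(rk[seq_len(n1)])
    sets <- utils::combn(length(v), n1)
    ws <- apply(sets, 2, function(i) sum(rk[i]))
    if (alternative == "greater") {
        mean(ws >= obs)
    } else {
        pl <- mean(ws <= obs)
        pu <- mean(ws >= obs)
        min(1, 2 * min(pl, pu))
    }
}

# exact hypergeometric upper tail by enumeration of all C(M, n) draws
oracle_hyper_p <- function(M, K, n, k) {
    draws <- utils::combn(M, n)
    hits <- colSums(draws <= K)   # items 1..K are "in the set"
    mean(hits >= k)
}

# Welch's t-test from the closed form
oracle_welch <- function(a, b) {
    na <- length(a); nb <- length(b)
    va <- stats::var(a); vb <- stats::var(b)
    se2 <- va / na + vb / nb
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t), df)
    list(t = t, df = df, p = p)
}

# brute-force binned-control module score: bins of equal size by data-wide
# mean, n_ctrl seeded draws per set gene, pooled unique control set
oracle_module_score <- function(mat, gene_set, nbin, n_ctrl, seed) {
    means <- rowMeans(mat)
    ord <- order(means)
    per <- nrow(mat) / nbin
    bin_of <- integer(nrow(mat))
    bin_of[ord] <- floor((seq_along(ord) - 1) / per) + 1
    names(bin_of) <- rownames(mat)
    set.seed(seed)
    ctrl <- character(0)
    for (g in gene_set) {
        members <- rownames(mat)[bin_of == bin_of[[g]]]
        ctrl <- c(ctrl, sample(members, min(n_ctrl, length(members))))
    }
    ctrl <- unique(ctrl)
    colMeans(mat[gene_set, , drop = FALSE]) -
        colMeans(mat[ctrl, , drop = FALSE])
}
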