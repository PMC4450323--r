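# Independent oracles used to verify the package's statistical
# primitives.  Each is written from the definition, not from the code it
# checks: Fisher p-values by log-factorial enumeration over all tables
# with the observed margins, signed-rank p-values by enumerating all 2^n
# sign assignments, hypergeometric tails by direct summation of
# binomial-coefficient products, window overlap by an all-pairs scan.

# Two-sided Fisher exact p for [[a, b], [c, d]] by exhaustive enumeration
# of tables with the same margins, using log-factorials only.
fisherOracle <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
    lp <- function(x) lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) +
        lgamma(n - c1 + 1) - lgamma(n + 1) - lgamma(x + 1) -
        lgamma(r1 - x + 1) - lgamma(c1 - x + 1) -
        lgamma(r2 - c1 + x + 1)
    xs <- max(0, c1 - r2):min(r1, c1)
    probs <- exp(lp(xs))
    sum(probs[probs <= exp(lp(a)) * (1 + 1e-7)])
}

# Exact two-sided signed-rank p by enumeration of all sign assignments
# (requires distinct non-zero absolute differences).
signedRankOracle <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    wObs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w <- as.vector(signs %*% r)
    mu <- n * (n + 1) / 4
    mean(abs(w - mu) >= abs(wObs - mu) - 1e-9)
}

# Upper-tail hypergeometric P(X >= x) by direct summation of
# choose-products.
hypergeomTailOracle <- function(N, K, n, x) {
    xs <- x:min(n, K)
    if (length(xs) == 0 || x > min(n, K)) return(0)
    sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# Quadratic all-pairs window/peak intersection (0-based half-open
# windows [pos - w/2, pos + w/2) against peaks [start, end)).
overlapOracle <- function(cpgs, peaks, window = 200) {
    half <- window / 2
    vapply(seq_len(nrow(cpgs)), function(i) {
        s <- cpgs$pos[i] - half
        e <- cpgs$pos[i] + half
        any(peaks$chrom == cpgs$chrom[i] &
            peaks$start < e & peaks$end > s)
    }, logical(1))
}

# Dense grid search over two-component mixtures of the panel, used as
# the deconvolution oracle on constructed two-type samples.
gridSearchTwoType <- function(R, b, i, j, step = 0.001) {
    ws <- seq(0, 1, by = step)
    obj <- vapply(ws, function(w)
        sum((R[, i] * w + R[, j] * (1 - w) - b)^2), numeric(1))
    ws[which.min(obj)]
}

# Convenience: small valid TriSampleCounts table.
makeCounts <- function(...) {
    rows <- list(...)
    df <- do.call(rbind, lapply(rows, as.data.frame))
    TriSampleCounts(df)
}
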