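## Small numeric helpers shared across modules.

# Unbiased (n-1) per-row variance without matrixStats.
rowVarsFast <- function(m) {
    n <- ncol(m)
    if (n < 2) return(rep(NA_real_, nrow(m)))
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (n - 1)
}

rowSdsFast <- function(m) sqrt(rowVarsFast(m))

# Standardize rows to zero mean, unit (n-1) variance; zero-variance rows -> 0.
rowStandardize <- function(m) {
    mu <- rowMeans(m)
    s <- rowSdsFast(m)
    s[s == 0 | is.na(s)] <- Inf
    (m - mu) / s
}

# Running mean over a centered window of w values, restricted to maximal
# runs of probes whose inter-probe gap (start[i+1] - end[i] - 1 bp) does not
# exceed maxGap. Windows truncate at run edges.
gapAwareRunningMean <- function(m, chrom, start, end, w, maxGap) {
    if (w <= 1L) return(m)
    half <- (w - 1L) %/% 2L
    out <- m
    gap <- c(Inf, start[-1] - end[-length(end)] - 1)
    newRun <- gap > maxGap | c(TRUE, chrom[-1] != chrom[-length(chrom)])
    runId <- cumsum(newRun)
    for (r in unique(runId)) {
        idx <- which(runId == r)
        k <- length(idx)
        if (k == 1L) next
        cs <- rbind(0, apply(m[idx, , drop = FALSE], 2, cumsum))
        lo <- pmax(seq_len(k) - half, 1L)
        hi <- pmin(seq_len(k) + half, k)
        out[idx, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
            (hi - lo + 1L)
    }
    out
}

# Jaccard distance between rows of a binary matrix; all-zero pairs get 0.
jaccardDist <- function(m) {
    m <- m * 1L
    inter <- tcrossprod(m)
    sums <- rowSums(m)
    union <- outer(sums, sums, "+") - inter
    d <- 1 - inter / union
    d[union == 0] <- 0
    diag(d) <- 0
    stats::as.dist(d)
}

# Two-sided Fisher test on a 2x2 built as
# [in-group & level, in-group & other; rest & level, rest & other].
fisher2x2 <- function(a, b, c, d) {
    tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
    ft <- stats::fisher.test(tab)
    list(counts = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

.assertOddWindow <- function(w) {
    if (w < 1L || w %% 2L == 0L)
        stop("smoothing window must be a positive odd integer")
}
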