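## Methylation-expression integration: DMR-gene matching by TSS proximity,
## correlation, resampling-based empirical significance thresholds, and
## rank-based two-group expression tests.

#' Match DMRs to genes by TSS proximity
#'
#' Pairs each DMR with every gene whose TSS lies within `maxDistance` bp of
#' the DMR interval (distance 0 inside the interval); many-to-many matches
#' are allowed.
#'
#' @param dmrs [DMRSet-class] or named [GenomicRanges::GRanges].
#' @param genes [GenomicRanges::GRanges] of TSS positions with `gene_id`.
#' @param maxDistance matching window, bp.
#' @return data.frame (dmr_id, gene_id) with the matched DMR fraction in
#'   `attr(, "matchedFraction")`.
#' @export
matchDmrToGenes <- function(dmrs, genes, maxDistance = 10000L) {
    gr <- if (is(dmrs, "DMRSet")) rowRanges(dmrs) else dmrs
    expanded <- gr_expand(gr, as.integer(maxDistance))
    hits <- suppressWarnings(findOverlaps(expanded, genes,
                                          ignore.strand = TRUE))
    pairs <- data.frame(
        dmr_id = names(gr)[queryHits(hits)],
        gene_id = mcols(genes)$gene_id[subjectHits(hits)],
        stringsAsFactors = FALSE)
    attr(pairs, "matchedFraction") <-
        length(unique(queryHits(hits))) / length(gr)
    pairs
}

# Rowwise correlation of aligned matrices (pairs along rows).
.pairCor <- function(a, b) {
    n <- ncol(a)
    rowSums(rowStandardize(a) * rowStandardize(b)) / (n - 1)
}

#' Correlate DMR methylation with gene expression
#'
#' Pearson or Spearman correlation per DMR-gene pair across the samples
#' shared between the two matrices; pairs with fewer than 5 shared samples
#' are dropped with a warning.
#'
#' @param dmrMeans matrix of DMR mean scores (rows named by DMR id).
#' @param expression matrix of expression values (rows named by gene id).
#' @param pairs data.frame (dmr_id, gene_id), e.g. from
#'   [matchDmrToGenes()].
#' @param method `"pearson"` or `"spearman"`.
#' @return `pairs` with an added `r` column.
#' @export
correlateDmrExpression <- function(dmrMeans, expression, pairs,
                                   method = c("pearson", "spearman")) {
    method <- match.arg(method)
    shared <- intersect(colnames(dmrMeans), colnames(expression))
    if (length(shared) < 5) {
        warning("fewer than 5 shared samples; all pairs dropped")
        out <- pairs[0, , drop = FALSE]
        out$r <- numeric(0)
        return(out)
    }
    keep <- pairs$dmr_id %in% rownames(dmrMeans) &
        pairs$gene_id %in% rownames(expression)
    if (!all(keep)) {
        warning(sum(!keep), " pair(s) with unknown DMR or gene dropped")
        pairs <- pairs[keep, , drop = FALSE]
    }
    a <- dmrMeans[pairs$dmr_id, shared, drop = FALSE]
    b <- expression[pairs$gene_id, shared, drop = FALSE]
    if (method == "spearman") {
        a <- t(apply(a, 1, rank))
        b <- t(apply(b, 1, rank))
    }
    pairs$r <- .pairCor(a, b)
    pairs
}

#' Empirical correlation-significance threshold by label resampling
#'
#' Builds a null by permuting expression sample labels `nResamples` times
#' and recomputing every pair correlation. The two-sided threshold is the
#' smallest observed |r| at which the estimated false discovery proportion
#' (mean null exceedance count over observed exceedance count) is at most
#' `fdr`; pairs with |r| at or above the threshold are significant.
#'
#' @inheritParams correlateDmrExpression
#' @param nResamples label permutations (values below 100 warn: unstable
#'   threshold).
#' @param fdr nominal false discovery rate.
#' @param seed RNG seed.
#' @return list with `threshold`, `pairs` (with r and significant),
#'   `fractionSignificant`, `fractionNegative` (among significant pairs).
#' @export
empiricalCorrelationThreshold <- function(dmrMeans, expression, pairs,
                                          nResamples = 1000L, fdr = 0.05,
                                          seed = 1L,
                                          method = c("pearson",
                                                     "spearman")) {
    method <- match.arg(method)
    if (nResamples < 100)
        warning("nResamples < 100: the empirical threshold is unstable")
    pairs <- correlateDmrExpression(dmrMeans, expression, pairs, method)
    shared <- intersect(colnames(dmrMeans), colnames(expression))
    a <- dmrMeans[pairs$dmr_id, shared, drop = FALSE]
    b <- expression[pairs$gene_id, shared, drop = FALSE]
    if (method == "spearman") {
        a <- t(apply(a, 1, rank))
        b <- t(apply(b, 1, rank))
    }
    az <- rowStandardize(a); bz <- rowStandardize(b)
    n <- length(shared)
    set.seed(seed)
    nullAbs <- numeric(0)
    for (i in seq_len(nResamples)) {
        perm <- sample(n)
        nullAbs <- c(nullAbs, abs(rowSums(az * bz[, perm, drop = FALSE]) /
                                      (n - 1)))
    }
    absR <- abs(pairs$r)
    cand <- sort(unique(absR))
    nullSorted <- sort(nullAbs)
    obsSorted <- sort(absR)
    threshold <- Inf
    for (t in cand) {
        nullCount <- (length(nullSorted) -
                      findInterval(t, nullSorted, left.open = TRUE)) /
            nResamples
        obsCount <- length(obsSorted) -
            findInterval(t, obsSorted, left.open = TRUE)
        if (obsCount > 0 && nullCount / obsCount <= fdr) {
            threshold <- t
            break
        }
    }
    pairs$significant <- absR >= threshold
    sig <- pairs[pairs$significant, , drop = FALSE]
    list(threshold = threshold, pairs = pairs,
         fractionSignificant = mean(pairs$significant),
         fractionNegative = if (nrow(sig) > 0) mean(sig$r < 0) else
             NA_real_)
}

#' Rank-sum test of expression between two groups
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test with tie correction.
#'
#' @param x numeric expression values.
#' @param group two-level grouping.
#' @return list with `statistic` and `p`.
#' @export
groupExpressionTest <- function(x, group) {
    group <- as.factor(group)
    stopifnot(nlevels(droplevels(group)) == 2)
    ht <- suppressWarnings(stats::wilcox.test(x ~ droplevels(group)))
    list(statistic = unname(ht$statistic), p = ht$p.value)
}
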