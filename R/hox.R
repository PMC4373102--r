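## Locus-level switch classification: k-means grouping of samples by
## two-block locus methylation, differential tests against a reference
## group with starburst coordinates, survival stratification, and
## pattern-level group comparisons.

.blockMeans <- function(mat, model) {
    ant <- model@dmrIds[seq_len(model@boundary)]
    post <- model@dmrIds[(model@boundary + 1L):length(model@dmrIds)]
    list(anterior = colMeans(mat[ant, , drop = FALSE]),
         posterior = colMeans(mat[post, , drop = FALSE]))
}

#' Classify samples by two-block locus methylation
#'
#' K-means (best of `nstart` restarts by within-cluster sum of squares)
#' over samples using their locus-DMR methylation vectors, then a
#' deterministic cluster-to-label mapping: each cluster's mean anterior
#' (mA) and posterior (mP) block methylation is compared with the cohort
#' medians; high mP with low mA is `posterior_only`, high mA with low mP is
#' `anterior_only`, both high is `pan`. An ambiguous mapping (e.g. both
#' blocks low, or two clusters mapping to one label) is an error listing
#' the cluster profiles.
#'
#' @param mat locus DMR methylation matrix (DMRs x samples).
#' @param model a [LocusModel-class].
#' @param k number of clusters (default 3).
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return list with `groups` (named factor), `consensusProfiles`
#'   (per-group per-DMR mean and sd), `clusterBlockMeans`.
#' @export
locusKmeans <- function(mat, model, k = 3L, seed = 1L, nstart = 50L) {
    validObject(model)
    if (!all(model@dmrIds %in% rownames(mat)))
        stop("locus DMR ids missing from the matrix")
    mat <- mat[model@dmrIds, , drop = FALSE]
    if (k > ncol(mat)) stop("k exceeds the number of samples")
    set.seed(seed)
    km <- stats::kmeans(t(mat), centers = k, nstart = nstart)
    bm <- .blockMeans(mat, model)
    labels <- character(k)
    prof <- matrix(NA_real_, k, 2, dimnames = list(NULL, c("mA", "mP")))
    for (cl in seq_len(k)) {
        idx <- km$cluster == cl
        prof[cl, ] <- c(mean(bm$anterior[idx]), mean(bm$posterior[idx]))
    }
    # dichotomize each block at the midrange of its cluster means; the
    # cohort median degenerates when one state covers half the samples
    cutA <- mean(range(prof[, "mA"]))
    cutP <- mean(range(prof[, "mP"]))
    for (cl in seq_len(k)) {
        hiA <- prof[cl, "mA"] > cutA
        hiP <- prof[cl, "mP"] > cutP
        labels[cl] <- if (hiP && !hiA) "posterior_only"
            else if (hiA && !hiP) "anterior_only"
            else if (hiA && hiP) "pan"
            else NA_character_
    }
    if (anyNA(labels) || anyDuplicated(labels))
        stop("ambiguous cluster-to-label mapping; cluster block means ",
             "(anterior, posterior): ",
             paste(apply(round(prof, 3), 1, paste, collapse = "/"),
                   collapse = "; "))
    groups <- factor(labels[km$cluster],
                     levels = c("posterior_only", "anterior_only", "pan"))
    names(groups) <- colnames(mat)
    cons <- lapply(levels(groups), function(g) {
        sub <- mat[, groups == g, drop = FALSE]
        data.frame(dmr_id = rownames(mat), mean = rowMeans(sub),
                   sd = rowSdsFast(sub), row.names = NULL)
    })
    names(cons) <- levels(groups)
    list(groups = groups, consensusProfiles = cons,
         clusterBlockMeans = prof)
}

# Vectorised Welch t-test of group g vs reference across matrix rows.
.welchRows <- function(mat, idx1, idx2) {
    m1 <- rowMeans(mat[, idx1, drop = FALSE])
    m2 <- rowMeans(mat[, idx2, drop = FALSE])
    v1 <- rowVarsFast(mat[, idx1, drop = FALSE]) / length(idx1)
    v2 <- rowVarsFast(mat[, idx2, drop = FALSE]) / length(idx2)
    t <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (length(idx1) - 1) +
                         v2^2 / (length(idx2) - 1))
    p <- 2 * stats::pt(-abs(t), df)
    data.frame(t = t, df = df, p = p, delta = m1 - m2)
}

#' Paired differential methylation and expression vs a reference group
#'
#' For each comparison group against the reference, Welch t-tests are run
#' per DMR (methylation) and per matched gene (expression), with
#' Benjamini-Hochberg correction within each data level. A pair is called
#' when both levels pass `FDR < alpha`. Starburst coordinates are the
#' signed -log10(q) per level (sign = direction of change vs reference);
#' counts of concordant pairs (methylation up, expression down) are
#' reported.
#'
#' @param methylation DMR methylation matrix (DMRs x samples).
#' @param expression expression matrix (genes x samples).
#' @param pairs data.frame (dmr_id, gene_id).
#' @param groups factor per sample.
#' @param reference reference group level.
#' @param alpha per-level FDR cutoff.
#' @return named list (one element per non-reference group) of data.frames
#'   with per-pair t statistics, q-values, starburst coordinates, `called`
#'   and `concordant`; the concordant/called counts are in
#'   `attr(, "summary")`.
#' @export
hoxGroupTests <- function(methylation, expression, pairs, groups,
                          reference = "posterior_only", alpha = 0.01) {
    groups <- as.factor(groups)
    stopifnot(reference %in% levels(groups))
    shared <- intersect(colnames(methylation), colnames(expression))
    shared <- shared[shared %in% names(groups)[!is.na(groups)]]
    g <- groups[shared]
    out <- list()
    for (lev in setdiff(levels(groups), reference)) {
        i1 <- which(g == lev); i2 <- which(g == reference)
        meth <- .welchRows(methylation[pairs$dmr_id, shared, drop = FALSE],
                           i1, i2)
        expr <- .welchRows(expression[pairs$gene_id, shared, drop = FALSE],
                           i1, i2)
        qm <- stats::p.adjust(meth$p, method = "BH")
        qe <- stats::p.adjust(expr$p, method = "BH")
        df <- data.frame(
            dmr_id = pairs$dmr_id, gene_id = pairs$gene_id,
            t_meth = meth$t, q_meth = qm, delta_meth = meth$delta,
            t_expr = expr$t, q_expr = qe, delta_expr = expr$delta,
            starburst_meth = sign(meth$delta) * -log10(qm),
            starburst_expr = sign(expr$delta) * -log10(qe),
            called = qm < alpha & qe < alpha)
        df$concordant <- df$called & df$delta_meth > 0 & df$delta_expr < 0
        attr(df, "summary") <- c(called = sum(df$called),
                                 concordant = sum(df$concordant))
        out[[lev]] <- df
    }
    out
}

#' Logrank test across sample groups
#'
#' K-group logrank test on survival with no covariate adjustment.
#'
#' @param time follow-up time.
#' @param event event indicator (1 = event, 0 = censored).
#' @param groups group label per sample.
#' @return list with `chisq`, `df`, `p`.
#' @export
logrankByGroup <- function(time, event, groups) {
    groups <- droplevels(as.factor(groups))
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ groups)
    df <- length(sd_$n) - 1
    list(chisq = unname(sd_$chisq), df = df,
         p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Pattern-level methylation comparison between locus groups
#'
#' Per-sample mean methylation over each pattern's DMRs, then pairwise
#' Welch t-tests between groups per pattern, Benjamini-Hochberg corrected
#' over all comparisons.
#'
#' @param dmrMeans DMR methylation matrix (DMRs x samples).
#' @param patterns pattern (1-3) per DMR.
#' @param groups group label per sample.
#' @return data.frame (pattern, group1, group2, t, p, q, delta).
#' @export
patternGroupComparison <- function(dmrMeans, patterns, groups) {
    groups <- droplevels(as.factor(groups))
    if (any(table(groups) < 2))
        stop("every group needs at least 2 samples")
    res <- list()
    for (p in sort(unique(patterns[!is.na(patterns)]))) {
        perSample <- colMeans(dmrMeans[which(patterns == p), ,
                                       drop = FALSE])
        levs <- levels(groups)
        for (i in seq_along(levs)) for (j in seq_along(levs)) {
            if (j <= i) next
            x <- perSample[groups == levs[i]]
            y <- perSample[groups == levs[j]]
            ht <- stats::t.test(x, y)
            res[[length(res) + 1]] <- data.frame(
                pattern = p, group1 = levs[i], group2 = levs[j],
                t = unname(ht$statistic), p = ht$p.value,
                delta = mean(x) - mean(y))
        }
    }
    out <- do.call(rbind, res)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out
}
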