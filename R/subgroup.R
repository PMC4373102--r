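## Sample subgrouping by bootstrap consensus clustering, subgroup-specific
## DMR selection by one-way ANOVA, archetype-based pattern assignment, and
## k-means consensus clustering for validation-style matrices.

.asFeatureMatrix <- function(x) {
    if (is(x, "DMRSet")) dmrMeans(x) else as.matrix(x)
}

#' Select the most variable features
#'
#' Keeps the `floor(fraction * n)` rows (at least one) with the highest
#' across-sample variance; ties are broken by row (genomic) order so the
#' selection is deterministic.
#'
#' @param x matrix (features x samples) or [DMRSet-class].
#' @param fraction fraction of rows kept, in (0, 1].
#' @return object of the same type, subset to the selected rows.
#' @export
selectTopVariance <- function(x, fraction = 0.25) {
    if (fraction <= 0 || fraction > 1)
        stop("fraction must lie in (0, 1]")
    mat <- .asFeatureMatrix(x)
    if (nrow(mat) < 4) stop("need at least 4 features")
    if (fraction == 1) return(x)
    k <- max(1L, floor(fraction * nrow(mat)))
    v <- rowVarsFast(mat)
    idx <- sort(order(-v, seq_along(v))[seq_len(k)])
    if (is(x, "DMRSet")) x[idx, ] else mat[idx, , drop = FALSE]
}

# 1 - Pearson correlation distance between columns; undefined correlations
# (constant profiles) become distance 1.
.corDist <- function(mat) {
    cc <- suppressWarnings(stats::cor(mat))
    if (anyNA(cc)) {
        warning("constant sample profile: undefined correlations set to ",
                "distance 1")
        cc[is.na(cc)] <- 0
    }
    stats::as.dist(1 - cc)
}

#' Bootstrap hierarchical consensus clustering of samples
#'
#' Draws `B` bootstrap resamples of features (rows, with replacement),
#' clusters samples in each by average-linkage hierarchical clustering on
#' 1 - Pearson correlation distance, and records pairwise co-clustering
#' frequencies at each `k` in `kRange`. The final assignment hierarchically
#' clusters `1 - consensus` and cuts at the `k` maximizing mean
#' within-cluster minus mean between-cluster consensus. With `B = 1` no
#' resampling is done (plain hierarchical clustering of the full matrix).
#'
#' @param x matrix (features x samples) or [DMRSet-class].
#' @param kRange candidate cluster numbers.
#' @param B bootstrap resamples.
#' @param seed RNG seed.
#' @param linkage hclust linkage method.
#' @return list with `assignment` (named integer), `k`, `stability`
#'   (per-sample mean co-clustering with co-members), `consensus` (matrix at
#'   the chosen k), `kScores`, `B`, `linkage`.
#' @export
bootstrapHclust <- function(x, kRange = 2:8, B = 1000L, seed = 1L,
                            linkage = "average") {
    mat <- .asFeatureMatrix(x)
    nS <- ncol(mat)
    if (nS < 2 * max(kRange))
        stop("need at least 2 * max(kRange) samples")
    set.seed(seed)
    co <- array(0, c(nS, nS, length(kRange)))
    for (b in seq_len(B)) {
        rows <- if (B == 1L) seq_len(nrow(mat))
                else sample(nrow(mat), replace = TRUE)
        hc <- stats::hclust(.corDist(mat[rows, , drop = FALSE]),
                            method = linkage)
        for (ki in seq_along(kRange)) {
            cl <- stats::cutree(hc, kRange[ki])
            co[, , ki] <- co[, , ki] + outer(cl, cl, "==")
        }
    }
    co <- co / B

    score <- numeric(length(kRange))
    labels <- vector("list", length(kRange))
    for (ki in seq_along(kRange)) {
        cons <- co[, , ki]
        hc <- stats::hclust(stats::as.dist(1 - cons), method = linkage)
        cl <- stats::cutree(hc, kRange[ki])
        ks <- sort(unique(cl))
        within <- vapply(ks, function(a) {
            i <- which(cl == a)
            if (length(i) < 2) return(1)
            m <- cons[i, i]
            mean(m[upper.tri(m)])
        }, numeric(1))
        between <- 0
        for (a in seq_along(ks)) for (b in seq_along(ks)) {
            if (b <= a) next
            between <- max(between,
                           mean(cons[cl == ks[a], cl == ks[b]]))
        }
        score[ki] <- min(within) - between
        labels[[ki]] <- cl
    }
    # worst-cluster within-consensus minus worst-pair between-consensus
    # plateaus under nested group structure (merging two stable groups is
    # also stable) and cliffs once a stable group is split arbitrarily, so
    # among ks on the plateau the finest stable partition is taken
    best <- max(which(score >= max(score) - 0.1))
    cl <- labels[[best]]
    cons <- co[, , best]
    stability <- vapply(seq_len(nS), function(i) {
        mates <- setdiff(which(cl == cl[i]), i)
        if (length(mates) == 0) 1 else mean(cons[i, mates])
    }, numeric(1))
    names(cl) <- names(stability) <- colnames(mat)
    list(assignment = cl, k = kRange[best], stability = stability,
         consensus = cons, kScores = stats::setNames(score, kRange),
         B = B, linkage = linkage)
}

#' One-way ANOVA screen for subgroup-specific features
#'
#' Classic equal-variance one-way ANOVA per feature across subgroup labels
#' (computed vectorised from group means), Benjamini-Hochberg corrected.
#'
#' @param x matrix (features x samples) or [DMRSet-class].
#' @param groups subgroup label per sample.
#' @param alpha BH q-value cutoff.
#' @return data.frame with feature, F, p, q, significant.
#' @export
anovaSubgroupDmrs <- function(x, groups, alpha = 0.05) {
    mat <- .asFeatureMatrix(x)
    groups <- as.factor(groups)
    if (any(table(groups) < 2))
        stop("every subgroup needs at least 2 samples")
    n <- ncol(mat); g <- nlevels(groups)
    counts <- as.integer(table(groups))
    groupSums <- t(rowsum(t(mat), groups))
    groupMeans <- sweep(groupSums, 2, counts, "/")
    grand <- rowMeans(mat)
    ssBetween <- rowSums(sweep((groupMeans - grand)^2, 2, counts, "*"))
    ssTotal <- rowSums((mat - grand)^2)
    ssWithin <- ssTotal - ssBetween
    Fstat <- (ssBetween / (g - 1)) / (ssWithin / (n - g))
    p <- stats::pf(Fstat, g - 1, n - g, lower.tail = FALSE)
    q <- stats::p.adjust(p, method = "BH")
    ids <- if (is.null(rownames(mat))) as.character(seq_len(nrow(mat)))
           else rownames(mat)
    data.frame(feature = ids, F = Fstat, p = p, q = q,
               significant = q < alpha, row.names = NULL)
}

# Archetypal subgroup-mean profiles of the three methylation patterns over
# subgroups 1..4 (centered): monotone decrease, subgroup-3-only, monotone
# increase.
.patternArchetypes <- function() {
    rbind(`1` = c(1.5, 0.5, -0.5, -1.5),
          `2` = c(-0.25, -0.25, 0.75, -0.25),
          `3` = c(-1.5, -0.5, 0.5, 1.5))
}

#' Partition subgroup-specific DMRs into three methylation patterns
#'
#' Clusters features (1 - Pearson correlation, Ward linkage) into three
#' clusters and labels each cluster by nearest-archetype cosine similarity
#' of its mean subgroup profile: pattern 1 decreases monotonically over
#' subgroups 1 to 4, pattern 2 peaks in subgroup 3, pattern 3 increases
#' monotonically. A non-bijective or tied archetype match is an error.
#'
#' @param x matrix of significant features x samples, or [DMRSet-class].
#' @param groups subgroup label (1-4) per sample.
#' @return list with `pattern` (named integer per feature), `counts`,
#'   `clusterProfiles` (cluster x subgroup mean matrix).
#' @export
derivePatterns <- function(x, groups) {
    mat <- .asFeatureMatrix(x)
    if (nrow(mat) < 3) stop("need at least 3 features")
    groups <- as.integer(as.character(groups))
    stopifnot(all(groups %in% 1:4))
    hc <- stats::hclust(.corDist(t(mat)), method = "ward.D2")
    cl <- stats::cutree(hc, 3)

    counts <- as.integer(table(factor(groups, 1:4)))
    profiles <- matrix(NA_real_, 3, 4)
    for (k in 1:3) {
        sub <- mat[cl == k, , drop = FALSE]
        perSample <- colMeans(sub)
        profiles[k, ] <- vapply(1:4, function(g)
            mean(perSample[groups == g]), numeric(1))
    }
    arch <- .patternArchetypes()
    cosine <- function(a, b) {
        a <- a - mean(a); b <- b - mean(b)
        sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    }
    sim <- matrix(NA_real_, 3, 3, dimnames = list(1:3, 1:3))
    for (k in 1:3) for (a in 1:3)
        sim[k, a] <- cosine(profiles[k, ], arch[a, ])
    assign <- apply(sim, 1, function(s) {
        top <- which(s == max(s))
        if (length(top) > 1)
            stop("tied archetype match; inspect cluster profiles manually")
        top
    })
    if (anyDuplicated(assign))
        stop("archetype matching is not one-to-one; ",
             "inspect cluster profiles manually")
    pattern <- stats::setNames(as.integer(assign[cl]), rownames(mat))
    list(pattern = pattern,
         counts = table(factor(pattern, 1:3)),
         clusterProfiles = profiles)
}

#' K-means consensus clustering of samples
#'
#' Repeated k-means on random sample subsets; pairwise co-clustering
#' frequencies (normalized by co-sampling counts) define a consensus matrix
#' whose hierarchical cut gives the final labels. With `subsample = 1` and
#' `nIter = 1` this reduces to a plain k-means partition.
#'
#' @param x matrix (features x samples) or [DMRSet-class].
#' @param k number of clusters (< number of samples).
#' @param nIter subsampled k-means repetitions.
#' @param subsample fraction of samples per repetition.
#' @param seed RNG seed.
#' @param nstart random k-means initializations per repetition.
#' @return list with `assignment`, `consensus`, `k`.
#' @export
kmeansConsensus <- function(x, k, nIter = 500L, subsample = 0.8,
                            seed = 1L, nstart = 10L) {
    mat <- .asFeatureMatrix(x)
    nS <- ncol(mat)
    if (k >= nS) stop("k must be smaller than the number of samples")
    set.seed(seed)
    co <- matrix(0, nS, nS)
    together <- matrix(0, nS, nS)
    m <- max(k + 1L, floor(subsample * nS))
    for (it in seq_len(nIter)) {
        idx <- if (subsample >= 1) seq_len(nS) else sample(nS, m)
        km <- stats::kmeans(t(mat[, idx, drop = FALSE]), centers = k,
                            nstart = nstart)
        together[idx, idx] <- together[idx, idx] + 1
        co[idx, idx] <- co[idx, idx] + outer(km$cluster, km$cluster, "==")
    }
    cons <- ifelse(together > 0, co / together, 0)
    diag(cons) <- 1
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    cl <- stats::cutree(hc, k)
    names(cl) <- colnames(mat)
    dimnames(cons) <- list(colnames(mat), colnames(mat))
    list(assignment = cl, consensus = cons, k = k)
}

#' Chi-square concordance of two sample labelings
#'
#' @param a,b label vectors over the same samples.
#' @return list with the contingency `table`, chi-square `statistic` and
#'   `p`.
#' @export
clusteringConcordance <- function(a, b) {
    stopifnot(length(a) == length(b))
    tab <- table(a, b)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(table = tab, statistic = unname(ct$statistic), p = ct$p.value)
}
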