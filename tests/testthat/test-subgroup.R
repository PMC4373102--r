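test_that("top-variance selection uses the floor rule with deterministic ties", {
    set.seed(1)
    mat <- matrix(rnorm(5453 * 4), 5453,
                  dimnames = list(sprintf("d%04d", 1:5453), letters[1:4]))
    top <- selectTopVariance(mat, 0.25)
    expect_equal(nrow(top), 1363L)       # floor(0.25 * 5453)
    v <- apply(mat, 1, var)
    oracle <- sort(order(-v)[1:1363])
    expect_identical(rownames(top), rownames(mat)[oracle])
    expect_identical(selectTopVariance(mat, 1), mat)
    expect_error(selectTopVariance(mat, 0), "fraction")
})

test_that("two separated blobs split perfectly with unit stability", {
    set.seed(2)
    u <- rnorm(50, sd = 2); v <- rnorm(50, sd = 2)
    mat <- cbind(u %o% rep(1, 10), v %o% rep(1, 10)) +
        matrix(rnorm(50 * 20, sd = 0.2), 50)
    colnames(mat) <- paste0("s", 1:20)
    bh <- bootstrapHclust(mat, kRange = 2, B = 50, seed = 1)
    expect_equal(bh$k, 2L)
    expect_equal(length(unique(bh$assignment[1:10])), 1L)
    expect_equal(length(unique(bh$assignment[11:20])), 1L)
    expect_true(all(bh$stability == 1))
})

test_that("B = 1 reduces to plain hierarchical clustering of the full matrix", {
    set.seed(3)
    mat <- matrix(rnorm(40 * 12), 40,
                  dimnames = list(NULL, paste0("s", 1:12)))
    bh <- bootstrapHclust(mat, kRange = 3, B = 1, seed = 1)
    plain <- cutree(hclust(as.dist(1 - cor(mat)), "average"), 3)
    # identical partitions up to label permutation
    expect_equal(mclust::adjustedRandIndex(bh$assignment, plain), 1)
})

test_that("the synthetic 4-subgroup cohort is recovered with high ARI", {
    co <- tinyCohort()
    top <- selectTopVariance(co$planted, 0.5)
    bh <- bootstrapHclust(top, kRange = 2:6, B = 200, seed = 5)
    expect_equal(bh$k, 4L)
    expect_gte(mclust::adjustedRandIndex(bh$assignment, co$subgroups),
               0.9)
})

test_that("vectorised ANOVA F matches the aov oracle", {
    set.seed(4)
    mat <- matrix(rnorm(20 * 24), 20)
    g <- factor(rep(1:4, each = 6))
    res <- anovaSubgroupDmrs(mat, g)
    for (i in 1:20) {
        fit <- summary(aov(mat[i, ] ~ g))[[1]]
        expect_equal(res$F[i], fit[["F value"]][1], tolerance = 1e-10)
        expect_equal(res$p[i], fit[["Pr(>F)"]][1], tolerance = 1e-10)
    }
    expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
})

test_that("ANOVA screen is calibrated under the null and powered for separation", {
    set.seed(5)
    null <- matrix(rnorm(400 * 40), 400)
    g <- factor(rep(1:4, each = 10))
    resNull <- anovaSubgroupDmrs(null, g, alpha = 0.05)
    expect_lte(mean(resNull$significant), 0.05 * 1.5)

    sep <- rbind(matrix(rep(c(0, 0, 5, 0), each = 10), 1) +
                     rnorm(40, sd = 0.1))
    resSep <- anovaSubgroupDmrs(rbind(sep, null[1:3, ]), g)
    expect_true(resSep$significant[1])
    expect_lt(resSep$q[1], 1e-10)

    expect_error(anovaSubgroupDmrs(null, factor(c(1, rep(2:4, c(13, 13,
                                                                13))))),
                 "at least 2")
})

test_that("noiseless archetype profiles are labeled exactly", {
    g <- rep(1:4, each = 5)
    arch <- rbind(p1 = (4 - g) / 3,
                  p2 = as.numeric(g == 3),
                  p3 = (g - 1) / 3)
    mat <- arch[rep(1:3, each = 10), ] +
        matrix(rnorm(30 * 20, sd = 1e-6), 30)
    rownames(mat) <- sprintf("d%02d", 1:30)
    dp <- derivePatterns(mat, g)
    expect_equal(unname(dp$pattern), rep(1:3, each = 10))
    # the subgroup-3-only profile is pattern 2 by definition
    expect_true(all(dp$pattern[11:20] == 2))
})

test_that("pattern labels are invariant to feature order and recover planted patterns", {
    co <- tinyCohort()
    an <- anovaSubgroupDmrs(co$planted, co$subgroups)
    sig <- co$planted[an$significant, , drop = FALSE]
    dp <- derivePatterns(sig, co$subgroups)
    truePat <- co$patterns[match(names(dp$pattern), names(co$dmrs))]
    expect_gte(mean(dp$pattern == truePat), 0.95)

    perm <- sample(nrow(sig))
    dp2 <- derivePatterns(sig[perm, ], co$subgroups)
    expect_equal(dp2$pattern[names(dp$pattern)], dp$pattern)
})

test_that("subgrouping is invariant to positive feature scaling", {
    co <- tinyCohort()
    top <- selectTopVariance(co$planted, 0.25)
    a <- bootstrapHclust(top, kRange = 4, B = 30, seed = 9)
    b <- bootstrapHclust(top * 7.3, kRange = 4, B = 30, seed = 9)
    expect_equal(a$assignment, b$assignment)
})

test_that("k-means consensus separates blobs and degenerates to plain k-means", {
    set.seed(6)
    centers <- matrix(c(0, 6, 12), 3)[rep(1:3, each = 8), ]
    mat <- t(centers + rnorm(24, sd = 0.3))
    mat <- rbind(mat, mat * 0.5)
    colnames(mat) <- paste0("s", 1:24)
    kc <- kmeansConsensus(mat, 3, nIter = 100, seed = 1)
    truth <- rep(1:3, each = 8)
    expect_equal(mclust::adjustedRandIndex(kc$assignment, truth), 1)
    off <- kc$consensus[truth[row(kc$consensus)] !=
                            truth[col(kc$consensus)]]
    expect_true(all(off == 0))

    kc1 <- kmeansConsensus(mat, 3, nIter = 1, subsample = 1, seed = 2,
                           nstart = 1)
    set.seed(2)
    km <- kmeans(t(mat), 3)
    expect_equal(mclust::adjustedRandIndex(kc1$assignment, km$cluster), 1)

    kc2 <- kmeansConsensus(mat, 3, nIter = 100, seed = 99)
    expect_gte(mclust::adjustedRandIndex(kc$assignment, kc2$assignment),
               0.95)
    expect_error(kmeansConsensus(mat, 30), "smaller")
})

test_that("clustering concordance matches a hand-computed chi-square", {
    a <- rep(c("x", "y"), c(12, 18))
    b <- rep(c("u", "v", "u", "v"), c(10, 2, 3, 15))
    cc <- clusteringConcordance(a, b)
    tab <- table(a, b)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    hand <- sum((tab - expected)^2 / expected)
    expect_equal(cc$statistic, hand, tolerance = 1e-10)
    expect_equal(cc$p, pchisq(hand, 1, lower.tail = FALSE),
                 tolerance = 1e-10)

    ident <- clusteringConcordance(rep(1:3, 10), rep(1:3, 10))
    expect_lt(ident$p, 1e-10)
})
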