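noiselessLocus <- function() {
    simulateHoxLocus(tinyConfig(), noiseSd = 0, high = 1, low = 0)
}

test_that("locus k-means recovers noiseless and default-noise labels", {
    hx0 <- noiselessLocus()
    lk0 <- locusKmeans(hx0$scores, hx0$model, seed = 1)
    expect_equal(as.character(lk0$groups), as.character(hx0$groups))

    co <- tinyCohort()
    hx <- simulateHoxLocus(co$cfg)
    lk <- locusKmeans(hx$scores, hx$model, seed = 1)
    expect_gte(mean(lk$groups == hx$groups), 0.95)

    lk2 <- locusKmeans(hx$scores, hx$model, seed = 99)
    expect_equal(lk$groups, lk2$groups)
})

test_that("locus k-means validates inputs and reports consensus profiles", {
    hx <- noiselessLocus()
    expect_error(locusKmeans(hx$scores, hx$model, k = 200), "exceeds")
    expect_error(locusKmeans(hx$scores[1:3, ], hx$model), "missing")

    lk <- locusKmeans(hx$scores, hx$model, seed = 1)
    prof <- lk$consensusProfiles$pan
    expect_equal(prof$mean, rep(1, 12), tolerance = 1e-12)
    expect_equal(prof$sd, rep(0, 12), tolerance = 1e-12)
})

test_that("group labels are invariant to DMR order and global shifts", {
    hx <- noiselessLocus()
    lk <- locusKmeans(hx$scores, hx$model, seed = 1)
    shifted <- locusKmeans(hx$scores + 5, hx$model, seed = 1)
    expect_equal(lk$groups, shifted$groups)
    perm <- sample(nrow(hx$scores))
    lkPerm <- locusKmeans(hx$scores[perm, ], hx$model, seed = 1)
    expect_equal(lk$groups, lkPerm$groups)
})

test_that("group tests call planted anti-correlated pairs with a (+,-) starburst", {
    set.seed(40)
    n <- 60
    groups <- factor(rep(c("posterior_only", "pan"), each = n / 2),
                     levels = c("posterior_only", "anterior_only", "pan"))
    names(groups) <- sprintf("s%02d", 1:n)
    meth <- matrix(rnorm(20 * n, sd = 0.3), 20,
                   dimnames = list(sprintf("d%02d", 1:20), names(groups)))
    expr <- matrix(rnorm(20 * n, sd = 0.3), 20,
                   dimnames = list(sprintf("g%02d", 1:20), names(groups)))
    meth[1, groups == "pan"] <- meth[1, groups == "pan"] + 3
    expr[1, groups == "pan"] <- expr[1, groups == "pan"] - 3
    pairs <- data.frame(dmr_id = rownames(meth), gene_id = rownames(expr))
    res <- hoxGroupTests(meth, expr, pairs, groups)$pan
    expect_true(res$called[1])
    expect_gt(res$starburst_meth[1], 2)
    expect_lt(res$starburst_expr[1], -2)
    # starburst coordinates reproduce the calls exactly
    expect_equal(res$called,
                 abs(res$starburst_meth) > 2 & abs(res$starburst_expr) > 2)
    expect_equal(attr(res, "summary")[["concordant"]], 1)
})

test_that("group tests are calibrated when groups are identical", {
    set.seed(41)
    calls <- replicate(10, {
        n <- 40
        groups <- factor(rep(c("posterior_only", "pan"), each = n / 2),
                         levels = c("posterior_only", "pan"))
        names(groups) <- sprintf("s%02d", 1:n)
        meth <- matrix(rnorm(50 * n), 50,
                       dimnames = list(sprintf("d%02d", 1:50),
                                       names(groups)))
        expr <- matrix(rnorm(50 * n), 50,
                       dimnames = list(sprintf("g%02d", 1:50),
                                       names(groups)))
        pairs <- data.frame(dmr_id = rownames(meth),
                            gene_id = rownames(expr))
        mean(hoxGroupTests(meth, expr, pairs, groups)$pan$called)
    })
    expect_lte(mean(calls), 0.01 * 1.5)
})

test_that("the Welch statistic matches stats::t.test", {
    set.seed(42)
    groups <- factor(rep(c("posterior_only", "pan"), c(12, 15)),
                     levels = c("posterior_only", "pan"))
    names(groups) <- sprintf("s%02d", seq_along(groups))
    meth <- matrix(rnorm(8 * 27), 8,
                   dimnames = list(paste0("d", 1:8), names(groups)))
    expr <- matrix(rnorm(8 * 27), 8,
                   dimnames = list(paste0("g", 1:8), names(groups)))
    pairs <- data.frame(dmr_id = rownames(meth), gene_id = rownames(expr))
    res <- hoxGroupTests(meth, expr, pairs, groups)$pan
    for (i in 1:8) {
        tt <- t.test(meth[i, groups == "pan"],
                     meth[i, groups == "posterior_only"])
        expect_equal(res$t_meth[i], unname(tt$statistic),
                     tolerance = 1e-10)
    }
})

test_that("the logrank test matches the observed-minus-expected oracle", {
    time <- c(2, 4, 5, 7, 9, 12, 3, 6, 8, 10, 14, 20)
    event <- c(1, 1, 0, 1, 1, 1, 1, 0, 1, 1, 1, 0)
    g <- rep(c("a", "b"), each = 6)
    got <- logrankByGroup(time, event, g)
    # textbook logrank: sum over event times of observed - expected in
    # group a, variance from the hypergeometric at each time
    o <- e <- v <- 0
    for (t in sort(unique(time[event == 1]))) {
        atRisk <- time >= t
        d <- sum(time == t & event == 1)
        n1 <- sum(atRisk & g == "a"); n <- sum(atRisk)
        o <- o + sum(time == t & event == 1 & g == "a")
        e <- e + d * n1 / n
        v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / max(n - 1, 1)
    }
    expect_equal(got$chisq, (o - e)^2 / v, tolerance = 1e-8)

    extreme <- logrankByGroup(c(rep(1, 10), rep(100, 10)),
                              c(rep(1, 10), rep(0, 10)),
                              rep(c("a", "b"), each = 10))
    expect_lt(extreme$p, 1e-4)
})

test_that("pattern-level group comparisons recover planted ordering", {
    co <- tinyCohort()
    hxGroups <- factor(
        ifelse(co$subgroups <= 2, "posterior_only",
               ifelse(co$subgroups == 3, "pan", "anterior_only")),
        levels = c("posterior_only", "anterior_only", "pan"))
    names(hxGroups) <- names(co$subgroups)
    res <- patternGroupComparison(co$planted, co$patterns, hxGroups)
    p1 <- res[res$pattern == 1 & res$group1 == "posterior_only", ]
    expect_true(all(p1$delta > 0))    # pattern 1 highest in low subgroups
    expect_true(all(p1$q < 0.001))

    g1 <- factor(rep(c("a", "b"), c(1, ncol(co$planted) - 1)))
    expect_error(patternGroupComparison(co$planted, co$patterns, g1),
                 "at least 2")
})

test_that("identical-group pattern comparisons stay null-calibrated", {
    set.seed(43)
    mat <- matrix(rnorm(30 * 40), 30,
                  dimnames = list(NULL, sprintf("s%02d", 1:40)))
    res <- patternGroupComparison(mat, rep(1:3, each = 10),
                                  rep(c("a", "b"), each = 20))
    expect_true(all(res$q > 0.01) || mean(res$q < 0.01) <= 0.34)
})
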