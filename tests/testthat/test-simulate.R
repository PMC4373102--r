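test_that("generator output is byte-identical under a fixed seed", {
    cfg <- tinyConfig(seed = 3L)
    a <- simulateProbeMatrix(cfg)
    b <- simulateProbeMatrix(cfg)
    expect_identical(probeScores(a$probes), probeScores(b$probes))
    expect_identical(rowRanges(a$probes), rowRanges(b$probes))
    expect_identical(a$truth@dmrRanges, b$truth@dmrRanges)
})

test_that("zero-noise pattern-2 DMRs separate subgroup 3 by exactly the effect size", {
    cfg <- simConfig(nDmrsPerPattern = c(4L, 4L, 4L), nNullProbes = 100L,
                     noiseSd = 0, effectSize = 1, seed = 2L)
    sim <- simulateProbeMatrix(cfg)
    pat <- mcols(sim$truth@dmrRanges)$pattern
    p2 <- sim$truth@dmrRanges[pat == 2]
    sc <- summarizeDmrs(sim$probes, p2)
    sub <- sim$truth@subgroups[colnames(sc)]
    for (i in seq_len(nrow(sc))) {
        expect_equal(unname(sc[i, sub == 3]), rep(1, sum(sub == 3)))
        expect_equal(unname(sc[i, sub %in% c(1, 2, 4)]),
                     rep(0, sum(sub %in% c(1, 2, 4))))
    }
})

test_that("planted pattern-1 and pattern-2 CpG densities differ as designed", {
    co <- tinyCohort()
    dmr <- co$dmrs
    probes <- rowRanges(co$probes)
    dens <- vapply(seq_along(dmr), function(i) {
        hits <- subjectHits(findOverlaps(dmr[i], probes))
        sum(mcols(probes)$cpg_count[hits]) / width(dmr[i])
    }, numeric(1))
    d1 <- dens[co$patterns == 1]
    d2 <- dens[co$patterns == 2]
    expect_lt(suppressWarnings(wilcox.test(d1, d2))$p.value, 0.01)
    expect_lt(median(d1), median(d2))
})

test_that("generator rejects chromosomes too short for the request", {
    expect_error(
        simulateProbeMatrix(simConfig(chromLengths = c(chr1 = 1e6))),
        "too short")
})

test_that("tracks recapitulate planted context by construction", {
    co <- tinyCohort()
    dmr <- co$dmrs
    cgi <- getTrack(co$tracks, "cgi")
    p2 <- dmr[co$patterns == 2]
    expect_true(all(overlapsAny(p2, cgi, type = "within")))
    ce <- chromEndFeatures(dmr[co$patterns == 1],
                           chromLengths(co$tracks))
    expect_equal(mean(ce$subtelomeric), 1.0)
    # flanking peaks never cover pattern-3 midpoints
    p3 <- dmr[co$patterns == 3]
    mids <- GRanges(seqnames(p3),
                    IRanges(floor((start(p3) + end(p3)) / 2), width = 1))
    pol <- getTrack(co$tracks, "rf.POLR2A.H1ESC")
    expect_false(any(overlapsAny(mids, pol)))
})

test_that("track generation rejects a chromosome mismatch", {
    co <- tinyCohort()
    truth <- co$truth
    badRanges <- truth@dmrRanges
    badTruth <- new("SyntheticTruth",
                    dmrRanges = GRanges("chrZ", IRanges(1000, 2000),
                                        dmr_id = "DMR0001",
                                        pattern = 1L),
                    subgroups = truth@subgroups,
                    exprPairs = truth@exprPairs)
    expect_error(simulateTracks(co$cfg, badTruth), "chromosomes")
})

test_that("expression generator plants exact negative correlation in the noiseless limit", {
    co <- tinyCohort()
    cfg1 <- tinyConfig(exprCorrFraction = 1, exprCorrTarget = 1 - 1e-12)
    ex <- simulateExpression(cfg1, co$truth, co$planted,
                             geneModels(co$tracks))
    for (i in seq_len(min(5, nrow(ex$pairs)))) {
        r <- cor(co$planted[ex$pairs$dmr_id[i], ],
                 ex$expression[ex$pairs$gene_id[i], ])
        expect_equal(r, -1, tolerance = 1e-6)
    }
    # fraction 0 plants nothing and the null r distribution stays tight
    cfg0 <- tinyConfig(exprCorrFraction = 0)
    ex0 <- simulateExpression(cfg0, co$truth, co$planted,
                              geneModels(co$tracks))
    expect_equal(nrow(ex0$pairs), 0L)
    rs <- apply(ex0$expression[1:200, ], 1, function(e)
        cor(e, co$planted[1, ]))
    expect_lt(quantile(abs(rs), 0.95), 3 / sqrt(ncol(co$planted)))
})

test_that("clinical generator with zero association strength gives uniform Fisher p", {
    co <- tinyCohort()
    ps <- vapply(1:40, function(s) {
        cfg <- tinyConfig(seed = 100L + s)
        st <- simulateClinical(cfg, co$truth, strength = 0)
        oneVsRestFisher(st, st$subgroup, "fgfr3", "mut", 1)$p
    }, numeric(1))
    # p-values should not pile up near zero
    expect_lt(mean(ps < 0.05), 0.2)
    expect_gt(mean(ps), 0.3)
})

test_that("survival is uniform under equal hazards and literal tables pass through", {
    co <- tinyCohort()
    ps <- vapply(1:60, function(s) {
        cfg <- tinyConfig(seed = 200L + s)
        st <- simulateClinical(cfg, co$truth,
                               hazardRatios = c(1, 1, 1, 1))
        logrankByGroup(st$survival_time, st$event, st$subgroup)$p
    }, numeric(1))
    expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
    lit <- data.frame(sample_id = c("a", "b"), stage = c("Ta", "MI"),
                      survival_time = c(10, 20), event = c(1L, 0L))
    expect_identical(simulateClinical(co$cfg, co$truth, literal = lit),
                     lit)
})

test_that("hox locus generator places block means exactly at configured levels without noise", {
    cfg <- tinyConfig()
    hx <- simulateHoxLocus(cfg, noiseSd = 0, high = 2, low = 0.5)
    ant <- hx$scores[1:7, ]
    post <- hx$scores[8:12, ]
    g <- hx$groups
    expect_true(all(ant[, g == "anterior_only"] == 2))
    expect_true(all(ant[, g == "posterior_only"] == 0.5))
    expect_true(all(post[, g == "pan"] == 2))
    expect_true(all(post[, g == "anterior_only"] == 0.5))
})

test_that("a boundary at the block edge is a degenerate locus", {
    expect_error(simulateHoxLocus(tinyConfig(), nAnterior = 0L),
                 "degenerate")
    expect_error(locusModel(c("a", "b"), boundary = 2L), "non-empty")
})

test_that("planted effect directions survive normalization", {
    cfg <- simConfig(nDmrsPerPattern = c(6L, 6L, 6L), nNullProbes = 500L,
                     effectSize = 2.5, noiseSd = 0.5, seed = 5L)
    sim <- simulateProbeMatrix(cfg)
    raw <- simulateRawIntensities(sim$probes, seed = 5L)
    norm <- normalizeProbes(raw$ip, raw$input, rowRanges(sim$probes))
    sortedDmrs <- sort(sim$truth@dmrRanges)
    means <- summarizeDmrs(norm, sortedDmrs)
    sub <- sim$truth@subgroups[colnames(means)]
    pat <- mcols(sortedDmrs)$pattern
    groupMeans <- function(i) vapply(1:4, function(g)
        mean(means[i, sub == g]), numeric(1))
    for (i in which(pat == 1))
        expect_identical(order(groupMeans(i), decreasing = TRUE), 1:4)
    for (i in which(pat == 3))
        expect_identical(order(groupMeans(i)), 1:4)
    for (i in which(pat == 2))
        expect_identical(which.max(groupMeans(i)), 3L)
})
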