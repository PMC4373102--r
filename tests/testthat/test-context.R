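bedGr <- function(chrom, bedStart, bedEnd, state = NULL, label = NULL) {
    gr <- GRanges(chrom, IRanges(bedStart + 1, bedEnd))
    if (!is.null(state)) mcols(gr)$state <- as.integer(state)
    if (!is.null(label)) mcols(gr)$label <- label
    gr
}

test_that("basewise overlap counts exact bases with half-open boundary splits", {
    q <- bedGr("chr1", 100, 200)
    t1 <- bedGr("chr1", 100, 200, state = 3)
    expect_equal(unname(basewiseOverlap(q, t1)[1, "3"]), 100L)

    t2 <- c(bedGr("chr1", 0, 150, state = 1), bedGr("chr1", 150, 300,
                                                    state = 2))
    got <- basewiseOverlap(q, t2)
    expect_equal(unname(got[1, ]), c(50L, 50L))

    expect_warning(basewiseOverlap(bedGr("chrZ", 0, 10), t2), "absent")
})

test_that("basewise overlap agrees with the per-base loop oracle", {
    set.seed(10)
    for (rep_ in 1:25) {
        q <- randomIntervals(5)
        track <- randomIntervals(8)
        mcols(track)$state <- sample(1:4, 8, replace = TRUE)
        got <- basewiseOverlap(q, track)
        for (i in 1:5) for (s in 1:4) {
            sub <- track[mcols(track)$state == s]
            exp_ <- 0L
            if (length(sub) > 0)
                exp_ <- sum(vapply(start(q)[i]:end(q)[i], function(pos)
                    any(start(sub) <= pos & end(sub) >= pos), logical(1)))
            col <- as.character(s)
            have <- if (col %in% colnames(got)) got[i, col] else 0L
            expect_equal(unname(have), exp_)
        }
    }
})

test_that("consensus state is the basewise majority with low-state tie-break", {
    m <- rbind(a = c(`3` = 400L, `13` = 100L),
               b = c(`3` = 250L, `13` = 250L))
    colnames(m) <- c("3", "13")
    cs <- consensusState(m)
    expect_equal(unname(cs["a"]), 3L)
    expect_equal(unname(cs["b"]), 3L)   # tie -> lowest state number
    m2 <- matrix(c(250L, 250L), 1, dimnames = list("x", c("7", "2")))
    expect_equal(unname(consensusState(m2)), 2L)

    set.seed(11)
    counts <- matrix(sample(0:100, 60, replace = TRUE), 10,
                     dimnames = list(NULL, as.character(c(3, 1, 10, 7, 2,
                                                          15))))
    cs2 <- consensusState(counts)
    for (i in 1:10) {
        states <- as.integer(colnames(counts))
        best <- min(states[counts[i, ] == max(counts[i, ])])
        expect_equal(unname(cs2[i]), best)
    }
})

test_that("window profiles aggregate per-anchor rows exactly", {
    anchors <- bedGr("chr1", c(1000, 2000), c(1100, 2100))
    track <- bedGr("chr1", 0, 5000)
    prof <- windowProfile(anchors, track, 400,
                          chromLens = c(chr1 = 10000))
    expect_equal(unname(profileFrequency(prof)), rep(1, 400))
    expect_equal(profileFrequency(prof),
                 colMeans(prof@anchorRows, na.rm = TRUE))
})

test_that("minus-strand anchors are flipped so downstream features appear at +offset", {
    tss <- GRanges("chr1", IRanges(5000, width = 1), strand = "-")
    feat <- bedGr("chr1", 4880, 4900)   # 100 bp downstream of a minus TSS
    prof <- windowProfile(tss, feat, 400, orientation = "strand",
                          chromLens = c(chr1 = 10000))
    occupied <- which(profileFrequency(prof) == 1)
    offsets <- occupied - 201L          # window position of the anchor
    expect_true(all(offsets >= 99 & offsets <= 120))
})

test_that("windows truncate at chromosome edges via the per-base denominator", {
    anchors <- bedGr("chr1", 49, 51)    # midpoint at 50
    track <- bedGr("chr1", 0, 200)
    prof <- windowProfile(anchors, track, 200,
                          chromLens = c(chr1 = 200))
    expect_true(all(is.na(prof@anchorRows[1, 1:49])))
    expect_equal(unname(profileFrequency(prof)[60:200]), rep(1, 141))
})

test_that("transition matrices are row-stochastic and track planted state resolution", {
    co <- tinyCohort()
    dmr <- co$truth@dmrRanges
    segs <- grep("^states\\.", trackNames(co$tracks), value = TRUE)
    states <- vapply(segs, function(s)
        consensusState(basewiseOverlap(dmr, getTrack(co$tracks, s))),
        integer(length(dmr)))
    colnames(states) <- sub("^states\\.", "", segs)
    tm <- transitionMatrix(states, "H1ESC")
    for (cell in names(tm)) {
        sums <- rowSums(tm[[cell]])
        expect_true(all(abs(sums[sums > 0] - 1) < 1e-12))
        expect_gte(tm[[cell]]["3", "12"], 0.9)
    }
    ident <- transitionMatrix(cbind(a = c(1L, 5L), b = c(1L, 5L)), "a")
    expect_equal(unname(ident$b["1", "1"]), 1)
    expect_equal(unname(ident$b["5", "5"]), 1)
})

test_that("repeat content and chromosome-end features match their oracles", {
    full <- bedGr("chr1", 0, 10000, label = "LINE1")
    d <- bedGr("chr1", 4000, 4400)
    rc <- repeatContent(d, full, 2000)
    expect_equal(rc$bases, 2000L)
    none <- suppressWarnings(
        repeatContent(d, bedGr("chr2", 0, 100, label = "LTR"), 2000))
    expect_equal(none$bases, 0L)
    expect_false(none$present)

    set.seed(12)
    dmrs <- randomIntervals(10, chromLen = 2000)
    reps <- randomIntervals(10, chromLen = 2000)
    got <- repeatContent(dmrs, reps, 200)
    merged <- GenomicRanges::reduce(reps)
    for (i in 1:10) {
        mid <- floor((start(dmrs)[i] + end(dmrs)[i]) / 2)
        exp_ <- bruteBaseOverlap("chrT", max(mid - 100, 1), mid + 99,
                                 as.character(seqnames(merged)),
                                 start(merged), end(merged))
        expect_equal(got$bases[i], exp_)
    }

    ce <- chromEndFeatures(bedGr("chr1", 0, 500), c(chr1 = 3e7))
    expect_equal(ce$distance, 0)
    expect_true(ce$subtelomeric)
    midDmr <- bedGr("chr1", 14999000, 15000000)
    ce2 <- chromEndFeatures(midDmr, c(chr1 = 3e7))
    expect_equal(ce2$distance, 14999000)
    expect_false(ce2$subtelomeric)
})

test_that("Fisher enrichment reproduces hypergeometric enumeration exactly", {
    expect_equal(signif(dmrscape:::fisher2x2(12, 6, 22, 58)$p, 2),
                 0.0026)
    expect_equal(dmrscape:::fisher2x2(0, 10, 0, 90)$p, 1)
    set.seed(13)
    for (rep_ in 1:40) {
        tab <- sample(0:15, 4, replace = TRUE)
        got <- dmrscape:::fisher2x2(tab[1], tab[2], tab[3], tab[4])$p
        expect_equal(got, enumFisher(tab[1], tab[2], tab[3], tab[4]),
                     tolerance = 1e-12)
        swapped <- dmrscape:::fisher2x2(tab[4], tab[3], tab[2], tab[1])$p
        expect_equal(got, swapped, tolerance = 1e-12)
    }
})

test_that("boolean and continuous feature enrichment behave per group", {
    set.seed(14)
    pattern <- rep(1:3, c(20, 20, 40))
    flag <- pattern == 2
    enr <- categoryEnrichment(flag, pattern)
    expect_equal(enr$direction[enr$group == "2"], "enriched")
    expect_lt(enr$p[enr$group == "2"], 1e-6)

    xs <- rnorm(80) + (pattern == 1) * 2
    kw <- categoryEnrichment(xs, pattern)
    expect_equal(kw$test, "kruskal-wallis")
    expect_lt(kw$p, 1e-4)
    mw <- categoryEnrichment(xs[pattern != 3], pattern[pattern != 3])
    expect_equal(mw$test, "mann-whitney")
})

test_that("gene-set enrichment matches phyper and its trivial limits", {
    universe <- sprintf("g%03d", 1:100)
    genes <- universe[1:20]
    expect_equal(genesetOverlap(genes, list(all = universe),
                                universe)$p, 1)
    res <- genesetOverlap(genes, list(hit = universe[1:10],
                                      miss = universe[91:95]), universe)
    expect_lt(res$p[res$set == "hit"], 1e-6)
    expect_gt(res$p[res$set == "miss"], 0.5)
    expect_equal(res$p[res$set == "hit"],
                 phyper(9, 10, 90, 20, lower.tail = FALSE),
                 tolerance = 1e-12)
})

test_that("context features flag planted CGI, shore and state context", {
    co <- tinyCohort()
    cfx <- contextFeatures(co$dmrs, co$tracks)
    p <- co$patterns
    expect_true(all(cfx$cgi_overlap[p == 2]))
    expect_gte(mean(cfx$shore_overlap[p == 3] & !cfx$cgi_overlap[p == 3]),
               0.95)
    expect_gte(mean(cfx$consensus_state.H1ESC[p == 2] == 3), 0.95)
    expect_gte(mean(cfx$consensus_state.H1ESC[p == 1] == 13), 0.95)
    expect_true(all(cfx$repeat_present[p == 1]))
    expect_equal(mean(cfx$subtelomeric[p == 1]), 1.0)
})
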