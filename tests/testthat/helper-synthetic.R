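suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(SummarizedExperiment)
    library(S4Vectors)
})

# Small shared cohort, built once per test run.
.fixtureEnv <- new.env(parent = emptyenv())

tinyConfig <- function(seed = 7L, ...) {
    simConfig(nDmrsPerPattern = c(20L, 20L, 40L), nNullProbes = 8000L,
              seed = seed, ...)
}

tinyCohort <- function() {
    if (is.null(.fixtureEnv$cohort)) {
        cfg <- tinyConfig()
        sim <- simulateProbeMatrix(cfg)
        tracks <- simulateTracks(cfg, sim$truth, nExtraCells = 3L)
        tumors <- names(sim$truth@subgroups)[sim$truth@subgroups > 0]
        planted <- summarizeDmrs(sim$probes, sim$truth@dmrRanges)[, tumors]
        dmrs <- sort(sim$truth@dmrRanges)   # genomic order, = planted rows
        .fixtureEnv$cohort <- list(
            cfg = cfg, probes = sim$probes, truth = sim$truth,
            tracks = tracks, tumors = tumors, planted = planted,
            subgroups = sim$truth@subgroups[tumors],
            dmrs = dmrs, patterns = mcols(dmrs)$pattern)
    }
    .fixtureEnv$cohort
}

# Cohort at the scale used for recovery checks: one-tenth of the study's
# per-pattern DMR counts, full sample layout.
studyScaleCohort <- function() {
    if (is.null(.fixtureEnv$study)) {
        cfg <- simConfig(nDmrsPerPattern = c(67L, 65L, 137L),
                         nNullProbes = 30000L, seed = 17L)
        sim <- simulateProbeMatrix(cfg)
        tracks <- simulateTracks(cfg, sim$truth)
        tumors <- names(sim$truth@subgroups)[sim$truth@subgroups > 0]
        planted <- summarizeDmrs(sim$probes, sim$truth@dmrRanges)[, tumors]
        dmrs <- sort(sim$truth@dmrRanges)
        .fixtureEnv$study <- list(
            cfg = cfg, probes = sim$probes, truth = sim$truth,
            tracks = tracks, tumors = tumors, planted = planted,
            subgroups = sim$truth@subgroups[tumors],
            dmrs = dmrs, patterns = mcols(dmrs)$pattern)
    }
    .fixtureEnv$study
}

# Brute-force per-base overlap count of one interval with a track subset.
bruteBaseOverlap <- function(chrom, from, to, trackChrom, trackFrom,
                             trackTo) {
    count <- 0L
    for (pos in from:to) {
        hit <- any(trackChrom == chrom & trackFrom <= pos & trackTo >= pos)
        count <- count + as.integer(hit)
    }
    count
}

# Random small GRanges on a short chromosome for oracle checks.
randomIntervals <- function(n, chromLen = 500L, chroms = "chrT",
                            maxWidth = 60L) {
    chrom <- sample(chroms, n, replace = TRUE)
    start <- sample.int(chromLen - maxWidth, n, replace = TRUE)
    width <- sample.int(maxWidth, n, replace = TRUE)
    GRanges(chrom, IRanges(start, width = width))
}

# Full-enumeration two-sided Fisher p (point-probability rule) for a 2x2.
enumFisher <- function(a, b, c_, d) {
    rowTot <- a + b
    colTot <- a + c_
    n <- a + b + c_ + d
    support <- max(0, colTot - (n - rowTot)):min(rowTot, colTot)
    probs <- stats::dhyper(support, rowTot, n - rowTot, colTot)
    pObs <- stats::dhyper(a, rowTot, n - rowTot, colTot)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}
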