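## Synthetic-cohort generator. Every input the pipeline consumes can be
## produced here with a known ground truth: a probe-level methylation score
## matrix tiling planted DMRs of three archetypal patterns, annotation
## tracks with the genomic context each pattern is expected to inhabit,
## correlated expression for a subset of pattern-3 DMRs, a clinical table
## with configurable association strengths, and a two-block HOX-like locus.

# Tumor subgroup mean score for a probe of a given pattern.
# pattern 1: monotone decrease over subgroups 1->4 (equally spaced);
# pattern 2: elevated only in subgroup 3; pattern 3: monotone increase.
# The monotone patterns are scaled by an amplitude factor (see
# .patternAmplitudes) so that all three patterns contribute equal
# between-sample variance given the subgroup sizes.
.patternMean <- function(pattern, subgroup, effect, amp = c(1, 1, 1)) {
    switch(pattern,
        `1` = amp[1] * effect * (4 - subgroup) / 3,
        `2` = ifelse(subgroup == 3, amp[2] * effect, 0),
        `3` = amp[3] * effect * (subgroup - 1) / 3)
}

# Amplitude multipliers equalizing the between-sample variance of the three
# pattern archetypes across the tumor cohort: pattern 2 keeps amplitude 1
# (its methylated/unmethylated separation is exactly the effect size), the
# equally-spaced monotone patterns are scaled to match its variance.
.patternAmplitudes <- function(nPerSubgroup) {
    w <- nPerSubgroup / sum(nPerSubgroup)
    varOf <- function(m) sum(w * m^2) - sum(w * m)^2
    v1 <- varOf(c(3, 2, 1, 0) / 3)
    v2 <- varOf(c(0, 0, 1, 0))
    v3 <- varOf(c(0, 1, 2, 3) / 3)
    c(sqrt(v2 / v1), 1, sqrt(v2 / v3))
}

# Normal urothelium mean: pattern-1 regions start fully methylated (tumors
# lose methylation), patterns 2-3 start unmethylated (tumors gain).
.normalMean <- function(pattern, effect) {
    if (pattern == "1") effect else 0
}

.sampleIds <- function(config) {
    nT <- sum(config@nPerSubgroup)
    c(sprintf("T%03d", seq_len(nT)),
      if (config@nNormals > 0) sprintf("N%02d", seq_len(config@nNormals)))
}

# Partition each chromosome into placement slots: subtelomeric slots (both
# 5-Mb ends) host pattern-1 DMRs, interior slots host everything else.
# Slots are wide enough that planted regions plus their flanking context
# (CpG islands, peaks, 2-kb repeat windows) never collide.
.placementSlots <- function(chromLengths, slotSize) {
    subtel <- interior <- list()
    for (chrom in names(chromLengths)) {
        L <- chromLengths[[chrom]]
        if (L < 2 * 5e6 + 4 * slotSize)
            stop("chromosome ", chrom, " too short to host requested probes ",
                 "(needs > ", 2 * 5e6 + 4 * slotSize, " bp)")
        s1 <- seq(1000, 5e6 - slotSize, by = slotSize)
        s2 <- seq(L - 5e6 + 1, L - slotSize - 1000, by = slotSize)
        si <- seq(5e6 + slotSize, L - 5e6 - 2 * slotSize, by = slotSize)
        subtel[[chrom]] <- data.frame(chrom = chrom, start = c(s1, s2))
        interior[[chrom]] <- data.frame(chrom = chrom, start = si)
    }
    list(subtel = do.call(rbind, subtel), interior = do.call(rbind, interior))
}

#' Simulate a probe-level methylation cohort with planted DMRs
#'
#' Generates a [ProbeMatrix-class] whose probes contiguously tile planted
#' DMRs (at least 4 probes each) of three methylation patterns plus
#' background probes carrying noise only. Pattern-1 DMRs are placed within
#' 5 Mb of chromosome ends and drawn CpG-poor; pattern-2 DMRs are CpG-dense
#' and elevated only in subgroup 3; pattern-3 DMRs increase monotonically
#' over subgroups 1 to 4. Gaussian noise of `noiseSd(config)` is added
#' everywhere. Output is byte-identical for identical configurations.
#'
#' @param config a [SimConfig-class].
#' @return list with elements `probes` ([ProbeMatrix-class]) and `truth`
#'   ([SyntheticTruth-class]).
#' @examples
#' sim <- simulateProbeMatrix(simConfig(nDmrsPerPattern = c(5, 5, 10),
#'                                      nNullProbes = 200))
#' sim$probes
#' @export
simulateProbeMatrix <- function(config) {
    validObject(config)
    set.seed(config@seed)
    sp <- config@probeSpacing
    nDmr <- config@nDmrsPerPattern
    slotSize <- 20L * sp + 6000L
    slots <- .placementSlots(config@chromLengths, slotSize)

    # null probes come in contiguous blocks so candidate runs can form
    nullBlockSizes <- integer(0)
    while (sum(nullBlockSizes) < config@nNullProbes)
        nullBlockSizes <- c(nullBlockSizes, sample(10:20, 1))
    if (length(nullBlockSizes))
        nullBlockSizes[length(nullBlockSizes)] <-
            nullBlockSizes[length(nullBlockSizes)] -
            (sum(nullBlockSizes) - config@nNullProbes)
    nullBlockSizes <- nullBlockSizes[nullBlockSizes > 0]

    if (nDmr[1] > nrow(slots$subtel))
        stop("chromosomes too short to host ", nDmr[1],
             " subtelomeric pattern-1 DMRs")
    nInteriorNeeded <- nDmr[2] + nDmr[3] + length(nullBlockSizes)
    if (nInteriorNeeded > nrow(slots$interior))
        stop("chromosomes too short to host ", nInteriorNeeded,
             " interior regions")

    subtelPick <- slots$subtel[sample(nrow(slots$subtel), nDmr[1]), ]
    interiorPick <- slots$interior[sample(nrow(slots$interior),
                                          nInteriorNeeded), ]
    p2Pick <- interiorPick[seq_len(nDmr[2]), ]
    p3Pick <- interiorPick[nDmr[2] + seq_len(nDmr[3]), ]
    nullPick <- interiorPick[nDmr[2] + nDmr[3] + seq_along(nullBlockSizes), ]

    buildRegions <- function(pick, nProbes) {
        data.frame(chrom = pick$chrom,
                   start = pick$start + sample(0:2000, nrow(pick),
                                               replace = TRUE),
                   nProbes = nProbes)
    }
    nProbesDmr <- function(n) pmin(5L + stats::rpois(n, 3), 20L)
    regions <- rbind(
        cbind(buildRegions(subtelPick, nProbesDmr(nDmr[1])), pattern = "1"),
        cbind(buildRegions(p2Pick, nProbesDmr(nDmr[2])), pattern = "2"),
        cbind(buildRegions(p3Pick, nProbesDmr(nDmr[3])), pattern = "3"),
        if (length(nullBlockSizes))
            cbind(buildRegions(nullPick, nullBlockSizes), pattern = "0"))

    # expand regions into contiguous probes of width == spacing
    regIdx <- rep(seq_len(nrow(regions)), regions$nProbes)
    within <- sequence(regions$nProbes) - 1L
    probeStart <- regions$start[regIdx] + within * sp
    probeChrom <- regions$chrom[regIdx]
    probePattern <- regions$pattern[regIdx]

    density <- config@cpgDensity[c(background = "background",
        `1` = "pattern1", `2` = "pattern2", `3` = "pattern3")[
        ifelse(probePattern == "0", "background", probePattern)]]
    cpg <- stats::rpois(length(probeStart), density * sp)

    ids <- .sampleIds(config)
    subgroups <- c(rep(1:4, config@nPerSubgroup),
                   rep(0L, config@nNormals))
    names(subgroups) <- ids
    baseMean <- matrix(0, length(probeStart), length(ids))
    amp <- .patternAmplitudes(config@nPerSubgroup)
    for (p in c("1", "2", "3")) {
        rows <- probePattern == p
        if (!any(rows)) next
        mu <- ifelse(subgroups == 0L,
                     .normalMean(p, config@effectSize) *
                         amp[as.integer(p)],
                     .patternMean(p, subgroups, config@effectSize, amp))
        baseMean[rows, ] <- matrix(mu, sum(rows), length(ids), byrow = TRUE)
    }
    score <- baseMean + matrix(stats::rnorm(length(baseMean),
                                            sd = config@noiseSd),
                               nrow(baseMean))
    colnames(score) <- ids

    gr <- GRanges(probeChrom, IRanges(probeStart, width = sp),
                  cpg_count = cpg)
    names(gr) <- sprintf("P%06d", seq_along(gr))
    pm <- ProbeMatrix(gr, score,
                      colData = DataFrame(
                          subgroup = ifelse(subgroups == 0L, NA_integer_,
                                            subgroups),
                          sample_type = ifelse(subgroups == 0L, "normal",
                                               "tumor"),
                          row.names = ids))

    dmr <- regions[regions$pattern != "0", ]
    dmrRanges <- GRanges(dmr$chrom,
                         IRanges(dmr$start, width = dmr$nProbes * sp),
                         dmr_id = sprintf("DMR%04d", seq_len(nrow(dmr))),
                         pattern = as.integer(dmr$pattern))
    names(dmrRanges) <- dmrRanges$dmr_id
    truth <- new("SyntheticTruth", dmrRanges = dmrRanges,
                 subgroups = subgroups,
                 exprPairs = data.frame(dmr_id = character(),
                                        gene_id = character(),
                                        sign = integer()))
    list(probes = pm, truth = truth)
}

#' Simulate a pure-noise probe matrix
#'
#' Background-only probes (no planted DMRs) arranged in contiguous blocks,
#' for calibration of the DMR caller's false-positive behavior.
#'
#' @param nProbes,nSamples matrix dimensions.
#' @param noiseSd Gaussian noise SD.
#' @param probeSpacing probe footprint, bp.
#' @param blockSize probes per contiguous block.
#' @param seed RNG seed.
#' @return A [ProbeMatrix-class].
#' @export
simulateNullProbeMatrix <- function(nProbes, nSamples, noiseSd = 0.5,
                                    probeSpacing = 100L, blockSize = 25L,
                                    seed = 1L) {
    set.seed(seed)
    nBlocks <- ceiling(nProbes / blockSize)
    blockStart <- 1 + (seq_len(nBlocks) - 1) * (blockSize * probeSpacing + 1e4)
    idx <- seq_len(nProbes)
    block <- (idx - 1) %/% blockSize
    within <- (idx - 1) %% blockSize
    start <- blockStart[block + 1] + within * probeSpacing
    gr <- GRanges("chr1", IRanges(start, width = probeSpacing),
                  cpg_count = stats::rpois(nProbes, 0.011 * probeSpacing))
    names(gr) <- sprintf("P%06d", idx)
    score <- matrix(stats::rnorm(nProbes * nSamples, sd = noiseSd), nProbes,
                    dimnames = list(names(gr),
                                    sprintf("S%03d", seq_len(nSamples))))
    ProbeMatrix(gr, score)
}

#' Emit two-channel pseudo-intensities for a score matrix
#'
#' Raw-signal mode of the generator: produces IP and input intensity
#' matrices whose per-probe log2 ratio equals the intended score plus an
#' array-level bias (per-array additive offset plus a CpG-count-linear
#' trend), to exercise the normalization steps.
#'
#' @param pm a [ProbeMatrix-class] holding the intended scores.
#' @param arrayOffset per-array additive offsets (log2 units); drawn
#'   `N(0, offsetSd)` when `NULL`.
#' @param offsetSd SD used to draw offsets.
#' @param cpgSlope per-array linear CpG-count trend coefficients; drawn
#'   `N(0, slopeSd)` when `NULL`.
#' @param slopeSd SD used to draw slopes.
#' @param seed RNG seed.
#' @return list with matrices `ip` and `input` plus the `offsets` and
#'   `slopes` used.
#' @export
simulateRawIntensities <- function(pm, arrayOffset = NULL, offsetSd = 0.5,
                                   cpgSlope = NULL, slopeSd = 0.02,
                                   seed = 1L) {
    set.seed(seed)
    nS <- ncol(pm)
    if (is.null(arrayOffset))
        arrayOffset <- stats::rnorm(nS, sd = offsetSd)
    if (is.null(cpgSlope))
        cpgSlope <- stats::rnorm(nS, sd = slopeSd)
    baseLog <- matrix(stats::rnorm(nrow(pm) * nS, mean = 10, sd = 0.3),
                      nrow(pm))
    input <- 2^baseLog
    bias <- matrix(arrayOffset, nrow(pm), nS, byrow = TRUE) +
        outer(rowData(pm)$cpg_count, cpgSlope)
    ip <- input * 2^(probeScores(pm) + bias)
    dimnames(ip) <- dimnames(input) <- dimnames(probeScores(pm))
    list(ip = ip, input = input, offsets = arrayOffset, slopes = cpgSlope)
}

.rfCells <- c("H1ESC", "GM12878", "HepG2", "K562", "HeLaS3")
.rfNames <- c("CTCF", "RAD21", "EZH2", "POLR2A", "TBP", "TAF1", "REST")
.extraSegCells <- c("GM12878", "HepG2", "K562", "HUVEC", "HMEC", "HSMM",
                    "NHEK", "NHLF")

# Split uncovered gaps of a segmentation into chunks with random background
# states (state 3 reserved for planted poised-promoter segments).
.fillSegmentationGaps <- function(featureSegs, chromLengths) {
    genome <- GRanges(names(chromLengths),
                      IRanges(1, unname(chromLengths)))
    gapsGr <- GenomicRanges::setdiff(genome, featureSegs)
    pieces <- list()
    bgStates <- c(1L, 2L, 4:15)
    bgWeights <- c(1, 1, 1, 1, 1, 1, 1, 2, 2, 3, 1, 8, 1, 1)
    for (i in seq_along(gapsGr)) {
        w <- width(gapsGr)[i]
        n <- max(1L, floor(w / 250000))
        cut <- floor(seq(0, w, length.out = n + 1))
        st <- start(gapsGr)[i] + cut[-length(cut)]
        en <- start(gapsGr)[i] + cut[-1] - 1
        pieces[[i]] <- GRanges(seqnames(gapsGr)[i], IRanges(st, en),
                               state = sample(bgStates, n, replace = TRUE,
                                              prob = bgWeights))
    }
    sort(c(featureSegs, do.call(c, pieces)))
}

#' Simulate genome annotation tracks matched to planted DMR context
#'
#' Builds the full annotation bundle the landscape analysis consumes, with
#' each planted pattern given its archetypal context: pattern-2 DMRs sit
#' inside CpG islands, inside poised-promoter (state 3) segments of the
#' reference cell line, under EZH2/CTCF/RAD21 peaks and conserved elements;
#' pattern-1 DMRs sit in heterochromatin (state 13) segments with local
#' LINE1/LTR repeats (their subtelomeric placement is fixed at probe
#' generation); pattern-3 DMRs sit in CpG-island shores with
#' POLR2A/TBP/TAF1 peaks flanking but not covering their midpoints. In the
#' additional cell-line segmentations, state-3 segments resolve to the
#' Polycomb-repressed state 12.
#'
#' @param config a [SimConfig-class].
#' @param truth the [SyntheticTruth-class] from [simulateProbeMatrix()].
#' @param nExtraCells number of additional cell-line segmentations (<= 8).
#' @param nBackgroundPeaks random background peaks per (RF, cell) track.
#' @return A [GenomeTracks-class].
#' @export
simulateTracks <- function(config, truth, nExtraCells = 8L,
                           nBackgroundPeaks = 100L) {
    set.seed(config@seed + 1L)
    dmr <- truth@dmrRanges
    if (!all(as.character(seqnames(dmr)) %in% names(config@chromLengths)))
        stop("truth chromosomes not present in config chromLengths")
    pat <- mcols(dmr)$pattern
    mid <- floor((start(dmr) + end(dmr)) / 2)
    chrom <- as.character(seqnames(dmr))
    L <- config@chromLengths

    interiorRandom <- function(n, width) {
        ch <- sample(names(L), n, replace = TRUE)
        st <- floor(stats::runif(n, 6e6, L[ch] - 6e6 - width))
        GRanges(ch, IRanges(st, width = width))
    }

    tracks <- list()

    p1 <- dmr[pat == 1]; p2 <- dmr[pat == 2]; p3 <- dmr[pat == 3]
    tracks$cgi <- sort(c(
        GRanges(seqnames(p2), IRanges(start(p2) - 200, end(p2) + 200)),
        GRanges(seqnames(p3), IRanges(end(p3) + 100, end(p3) + 900)),
        interiorRandom(200L, 800L)))

    tracks$ncec <- sort(c(
        GRanges(seqnames(p2), IRanges(start(p2) - 100, end(p2) + 100)),
        interiorRandom(300L, 300L)))

    repPick <- sample(c("LINE1", "LTR"), length(p1), replace = TRUE)
    repStart <- start(p1) + sample(0:100, length(p1), replace = TRUE)
    tracks$repeats <- sort(c(
        GRanges(seqnames(p1), IRanges(repStart, width = 350),
                label = repPick),
        {
            bg <- interiorRandom(300L, 350L)
            mcols(bg)$label <- sample(c("LINE1", "LTR"), 300L, replace = TRUE)
            bg
        }))

    featureSegs <- sort(c(
        GRanges(seqnames(p1), IRanges(start(p1) - 300, end(p1) + 300),
                state = 13L),
        GRanges(seqnames(p2), IRanges(start(p2) - 500, end(p2) + 500),
                state = 3L),
        GRanges(seqnames(p3), IRanges(start(p3) - 200, end(p3) + 200),
                state = 2L)))
    refSeg <- .fillSegmentationGaps(featureSegs, L)
    tracks[["states.H1ESC"]] <- refSeg
    for (cell in .extraSegCells[seq_len(nExtraCells)]) {
        alt <- refSeg
        mcols(alt)$state[mcols(alt)$state == 3L] <- 12L
        tracks[[paste0("states.", cell)]] <- alt
    }

    coverPeak <- function(sub) GRanges(seqnames(sub),
        IRanges(floor((start(sub) + end(sub)) / 2) - 300, width = 600))
    flankPeaks <- function(sub) {
        m <- floor((start(sub) + end(sub)) / 2)
        c(GRanges(seqnames(sub), IRanges(m - 900, m - 301)),
          GRanges(seqnames(sub), IRanges(m + 301, m + 900)))
    }
    for (cell in .rfCells) {
        isRef <- cell == "H1ESC"
        for (rf in .rfNames) {
            peaks <- interiorRandom(nBackgroundPeaks, 600L)
            if (rf %in% c("CTCF", "RAD21", "EZH2")) {
                keep <- if (isRef) rep(TRUE, length(p2)) else
                    stats::runif(length(p2)) < 0.5
                peaks <- c(peaks, coverPeak(p2[keep]))
            }
            if (rf == "REST") {
                keep <- seq_along(p2) %in%
                    seq_len(max(1L, floor(length(p2) * 0.3)))
                peaks <- c(peaks, coverPeak(p2[keep]))
            }
            if (rf %in% c("POLR2A", "TBP", "TAF1")) {
                keep <- stats::runif(length(p3)) < 0.8
                peaks <- c(peaks, flankPeaks(p3[keep]))
            }
            tracks[[paste0("rf.", rf, ".", cell)]] <- sort(peaks)
        }
        dhs <- interiorRandom(nBackgroundPeaks, 400L)
        keep2 <- if (isRef) rep(TRUE, length(p2)) else
            stats::runif(length(p2)) < 0.6
        dhs <- c(dhs, coverPeak(p2[keep2]), flankPeaks(p3))
        tracks[[paste0("dhs.", cell)]] <- sort(dhs)
    }

    geneFor <- function(sub) {
        m <- floor((start(sub) + end(sub)) / 2)
        tss <- pmin(pmax(m + round(stats::runif(length(sub), -2000, 2000)),
                         1), L[as.character(seqnames(sub))])
        GRanges(seqnames(sub), IRanges(tss, width = 1),
                strand = sample(c("+", "-"), length(sub), replace = TRUE),
                gene_id = paste0("G_", names(sub)))
    }
    bgGenes <- interiorRandom(500L, 1L)
    strand(bgGenes) <- sample(c("+", "-"), 500L, replace = TRUE)
    mcols(bgGenes)$gene_id <- sprintf("BG%04d", seq_len(500L))
    genes <- sort(c(geneFor(p3), geneFor(p2), bgGenes))

    GenomeTracks(tracks = tracks, chromLengths = L, geneModels = genes)
}

#' Simulate a gene expression matrix with planted DMR correlations
#'
#' For a configured fraction of pattern-3 DMRs, the matched gene's
#' expression is generated as a negatively correlated transform of the
#' DMR's measured per-sample mean methylation (population correlation
#' `-exprCorrTarget(config)`); all other genes are independent noise.
#'
#' @param config a [SimConfig-class].
#' @param truth the [SyntheticTruth-class].
#' @param dmrMeans matrix of planted-DMR mean scores (rows named by DMR id,
#'   columns = tumor samples), e.g. from [summarizeDmrs()].
#' @param genes [GenomicRanges::GRanges] of gene models (from
#'   [simulateTracks()]).
#' @return list with `expression` (genes x samples matrix), `pairs`
#'   (planted DMR-gene pairs), and the updated `truth`.
#' @export
simulateExpression <- function(config, truth, dmrMeans, genes) {
    set.seed(config@seed + 2L)
    samples <- colnames(dmrMeans)
    geneIds <- mcols(genes)$gene_id
    p3 <- names(truth@dmrRanges)[mcols(truth@dmrRanges)$pattern == 3]
    p3 <- p3[p3 %in% rownames(dmrMeans) & paste0("G_", p3) %in% geneIds]
    nPlant <- floor(config@exprCorrFraction * length(p3))
    planted <- if (nPlant > 0) sample(p3, nPlant) else character()

    expr <- matrix(stats::rnorm(length(geneIds) * length(samples)),
                   length(geneIds),
                   dimnames = list(geneIds, samples))
    r <- config@exprCorrTarget
    for (d in planted) {
        z <- as.numeric(scale(dmrMeans[d, ]))
        expr[paste0("G_", d), ] <- -r * z +
            sqrt(1 - r^2) * stats::rnorm(length(samples))
    }
    pairs <- data.frame(dmr_id = planted,
                        gene_id = if (length(planted))
                            paste0("G_", planted) else character(),
                        sign = rep(-1L, length(planted)))
    truth@exprPairs <- pairs
    list(expression = expr, pairs = pairs, truth = truth)
}

#' Simulate a clinical and survival annotation table
#'
#' Categorical annotations (stage, grade, TP53/FGFR3 mutation, expression
#' subtype, epitype) are drawn with subgroup-conditional probabilities taken
#' by default from the packaged cohort characteristics table; `strength`
#' interpolates between those conditionals (1) and the marginal
#' distribution (0, no association). Survival times are exponential with
#' subgroup-specific hazards and administrative uniform censoring.
#'
#' @param config a [SimConfig-class].
#' @param truth the [SyntheticTruth-class] carrying subgroup labels.
#' @param strength association strength in [0, 1].
#' @param hazardRatios per-subgroup hazard multipliers.
#' @param baseHazard baseline event hazard per day.
#' @param censorRange range of uniform administrative censoring times, days.
#' @param literal optional literal table: validated and returned unchanged
#'   (deterministic injection).
#' @return data.frame with sample_id, subgroup, stage, grade, tp53, fgfr3,
#'   lund_subtype, epitype, survival_time, event.
#' @export
simulateClinical <- function(config, truth, strength = 1,
                             hazardRatios = c(1, 1, 2, 3),
                             baseHazard = log(2) / 1825,
                             censorRange = c(1000, 4000),
                             literal = NULL) {
    if (!is.null(literal)) {
        validateSampleTable(literal)
        return(literal)
    }
    stopifnot(strength >= 0, strength <= 1)
    set.seed(config@seed + 3L)
    tab <- table1Counts()
    sub <- truth@subgroups[truth@subgroups > 0]
    n <- length(sub)

    drawAnnotation <- function(annotation) {
        rows <- tab[tab$annotation == annotation, ]
        probs <- as.matrix(rows[, c("sg1", "sg2", "sg3", "sg4")])
        marg <- rows$total / sum(rows$total)
        out <- character(n)
        for (g in 1:4) {
            pg <- probs[, g] / sum(probs[, g])
            p <- strength * pg + (1 - strength) * marg
            idx <- sub == g
            out[idx] <- sample(rows$level, sum(idx), replace = TRUE, prob = p)
        }
        out
    }

    time <- stats::rexp(n, rate = baseHazard * hazardRatios[sub])
    cens <- stats::runif(n, censorRange[1], censorRange[2])
    df <- data.frame(
        sample_id = names(sub),
        subgroup = as.integer(sub),
        stage = drawAnnotation("stage"),
        grade = drawAnnotation("grade"),
        tp53 = drawAnnotation("tp53"),
        fgfr3 = drawAnnotation("fgfr3"),
        lund_subtype = drawAnnotation("lund_subtype"),
        epitype = drawAnnotation("epitype"),
        survival_time = pmin(time, cens),
        event = as.integer(time <= cens),
        stringsAsFactors = FALSE)
    validateSampleTable(df)
    df
}

#' Simulate a two-block HOX-like locus
#'
#' An ordered locus of anterior and posterior DMR blocks split at a declared
#' boundary, with three planted sample groups: `posterior_only` (posterior
#' block methylated), `anterior_only` (anterior block methylated) and `pan`
#' (both). Block means sit at `high`/`low` with Gaussian noise.
#'
#' @param config a [SimConfig-class] supplying defaults for `high`
#'   (`effectSize`) and `noiseSd`.
#' @param nAnterior,nPosterior DMRs per block.
#' @param groupSizes named sizes for posterior_only/anterior_only/pan.
#' @param high,low methylated / unmethylated block mean scores.
#' @param noiseSd per-value noise SD; defaults to `noiseSd(config)`.
#' @return list with `scores` (DMRs x samples), `model`
#'   ([LocusModel-class]), and `groups` (factor of planted labels).
#' @export
simulateHoxLocus <- function(config, nAnterior = 7L, nPosterior = 5L,
                             groupSizes = c(posterior_only = 36L,
                                            anterior_only = 27L, pan = 35L),
                             high = config@effectSize, low = 0,
                             noiseSd = config@noiseSd) {
    set.seed(config@seed + 4L)
    nD <- nAnterior + nPosterior
    if (nAnterior < 1L || nPosterior < 1L)
        stop("degenerate locus: both anterior and posterior blocks must ",
             "contain at least one DMR")
    ids <- sprintf("hox_dmr_%02d", seq_len(nD))
    model <- locusModel(ids, boundary = nAnterior, locusName = "HOXA-like")
    groups <- factor(rep(names(groupSizes), groupSizes),
                     levels = c("posterior_only", "anterior_only", "pan"))
    samples <- sprintf("T%03d", seq_along(groups))
    anteriorHigh <- c(posterior_only = low, anterior_only = high, pan = high)
    posteriorHigh <- c(posterior_only = high, anterior_only = low, pan = high)
    mu <- matrix(0, nD, length(groups))
    mu[seq_len(nAnterior), ] <- rep(anteriorHigh[as.character(groups)],
                                    each = nAnterior)
    mu[nAnterior + seq_len(nPosterior), ] <-
        rep(posteriorHigh[as.character(groups)], each = nPosterior)
    scores <- mu + matrix(stats::rnorm(length(mu), sd = noiseSd), nD)
    dimnames(scores) <- list(ids, samples)
    names(groups) <- samples
    list(scores = scores, model = model, groups = groups)
}

#' Simulate the full synthetic cohort in one call
#'
#' Convenience wrapper chaining [simulateProbeMatrix()], [simulateTracks()],
#' [summarizeDmrs()] over the planted regions, [simulateExpression()] and
#' [simulateClinical()].
#'
#' @param config a [SimConfig-class].
#' @param ... forwarded to [simulateTracks()].
#' @return list with `probes`, `truth`, `tracks`, `plantedMeans`,
#'   `expression`, `samples`.
#' @export
simulateCohort <- function(config, ...) {
    sim <- simulateProbeMatrix(config)
    tracks <- simulateTracks(config, sim$truth, ...)
    tumorIds <- names(sim$truth@subgroups)[sim$truth@subgroups > 0]
    planted <- summarizeDmrs(sim$probes, sim$truth@dmrRanges)[, tumorIds,
                                                              drop = FALSE]
    ex <- simulateExpression(config, sim$truth, planted,
                             geneModels(tracks))
    samples <- simulateClinical(config, ex$truth)
    list(probes = sim$probes, truth = ex$truth, tracks = tracks,
         plantedMeans = planted, expression = ex$expression,
         samples = samples)
}
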