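## Variance-based between-sample DMR calling with a permutation null
## matched on local CpG density.

#' DMR-calling parameters
#'
#' @param minProbes minimum consecutive above-threshold probes per
#'   candidate region.
#' @param maxGapBp maximum inter-probe gap inside a candidate run.
#' @param variancePercentile probes with across-sample variance at or above
#'   this percentile (of all probes) seed candidates; ties at the threshold
#'   are included.
#' @param nPermutations same-size probe sets drawn per candidate from its
#'   CpG-density bin.
#' @param densityBins number of quantile bins of local CpG density
#'   (CpG count / probe length) computed over all probes.
#' @param fdrAlpha Benjamini-Hochberg cutoff on candidate q-values.
#' @param mergeDistanceBp surviving regions closer than this are merged.
#' @param minLengthBp minimum candidate span, bp.
#' @param seed RNG seed for the permutation null.
#' @return a validated parameter list.
#' @export
dmrCallParams <- function(minProbes = 4L, maxGapBp = 500L,
                          variancePercentile = 90, nPermutations = 1000L,
                          densityBins = 10L, fdrAlpha = 0.05,
                          mergeDistanceBp = 200L, minLengthBp = 500L,
                          seed = 1L) {
    stopifnot(minProbes >= 1, maxGapBp >= 1, nPermutations >= 1,
              densityBins >= 1, mergeDistanceBp >= 0, minLengthBp >= 1,
              variancePercentile > 0, variancePercentile < 100,
              fdrAlpha > 0, fdrAlpha < 1)
    list(minProbes = as.integer(minProbes), maxGapBp = as.integer(maxGapBp),
         variancePercentile = variancePercentile,
         nPermutations = as.integer(nPermutations),
         densityBins = as.integer(densityBins), fdrAlpha = fdrAlpha,
         mergeDistanceBp = as.integer(mergeDistanceBp),
         minLengthBp = as.integer(minLengthBp), seed = as.integer(seed))
}

# Maximal runs of consecutive above-threshold probes with bounded gaps.
.candidateRuns <- function(above, chrom, start, end, maxGap) {
    n <- length(above)
    gap <- c(Inf, start[-1] - end[-n] - 1)
    sameRun <- above &
        c(FALSE, above[-n]) &
        gap <= maxGap &
        c(FALSE, chrom[-1] == chrom[-n])
    runStart <- which(above & !sameRun)
    if (length(runStart) == 0) return(list())
    runId <- cumsum(above & !sameRun)
    runId[!above] <- 0L
    split(which(above), runId[above])
}

#' Call between-sample differentially methylated regions
#'
#' Candidate regions are maximal runs of at least `minProbes` consecutive
#' probes whose across-sample variance (unbiased, n-1) lies at or above the
#' `variancePercentile` of all probe variances, with inter-probe gaps at
#' most `maxGapBp` and span at least `minLengthBp`. Each candidate's
#' statistic (mean member-probe variance) is compared with `nPermutations`
#' random same-size probe sets drawn from the candidate's local CpG-density
#' bin (quantile bins of CpG count per bp over all probes); the empirical p
#' uses the add-one estimator. Benjamini-Hochberg-surviving candidates
#' closer than `mergeDistanceBp` are merged and per-sample mean scores
#' attached.
#'
#' @param pm a normalized [ProbeMatrix-class].
#' @param params a [dmrCallParams()] list.
#' @param samples columns used for variance computation (default: columns
#'   annotated `sample_type == "tumor"`, else all); means are attached for
#'   all columns of `pm`.
#' @return A [DMRSet-class]; empty (zero rows) for a constant matrix.
#' @export
callDmrs <- function(pm, params = dmrCallParams(), samples = NULL) {
    if (is.null(samples)) {
        ty <- colData(pm)$sample_type
        samples <- if (!is.null(ty) && any(ty == "tumor"))
            colnames(pm)[ty == "tumor"] else colnames(pm)
    }
    if (length(samples) < 8)
        stop("DMR calling requires at least 8 samples")
    mat <- probeScores(pm)[, samples, drop = FALSE]
    rr <- rowRanges(pm)
    chrom <- as.character(seqnames(rr))
    v <- rowVarsFast(mat)

    emptySet <- function() DMRSet(
        GRanges(character(), IRanges(), n_probes = integer(),
                stat = numeric(), empirical_p = numeric(),
                fdr_q = numeric(), cpg_per_bp = numeric()),
        matrix(numeric(), 0, ncol(pm), dimnames = list(NULL, colnames(pm))))

    if (all(v < .Machine$double.eps)) return(emptySet())
    thr <- stats::quantile(v, params$variancePercentile / 100, names = FALSE)
    runs <- .candidateRuns(v >= thr, chrom, start(rr), end(rr),
                           params$maxGapBp)
    runs <- Filter(function(idx) length(idx) >= params$minProbes, runs)
    runs <- Filter(function(idx) {
        end(rr)[idx[length(idx)]] - start(rr)[idx[1]] + 1 >=
            params$minLengthBp
    }, runs)
    if (length(runs) == 0) return(emptySet())

    # permutation null matched on local CpG density
    density <- mcols(rr)$cpg_count / width(rr)
    breaks <- unique(stats::quantile(density,
                                     seq(0, 1, length.out =
                                             params$densityBins + 1)))
    bin <- if (length(breaks) > 2)
        cut(density, breaks, include.lowest = TRUE, labels = FALSE)
    else rep(1L, length(density))
    nBins <- max(bin)
    binMembers <- split(seq_along(density), bin)

    set.seed(params$seed)
    stat <- vapply(runs, function(idx) mean(v[idx]), numeric(1))
    pEmp <- numeric(length(runs))
    B <- params$nPermutations
    for (i in seq_along(runs)) {
        idx <- runs[[i]]
        b <- bin[idx][which.max(tabulate(bin[idx], nBins))]
        pool <- binMembers[[as.character(b)]]
        widen <- 1L
        while (length(pool) < length(idx) && widen < nBins) {
            warning("CpG-density bin ", b, " too small; widened to ",
                    "adjacent bins")
            nb <- as.character(c(b - widen, b + widen))
            pool <- unique(c(pool, unlist(binMembers[
                nb[nb %in% names(binMembers)]])))
            widen <- widen + 1L
        }
        draws <- matrix(sample(pool, length(idx) * B, replace = TRUE), B)
        nullStat <- rowMeans(matrix(v[draws], B))
        pEmp[i] <- (1 + sum(nullStat >= stat[i])) / (1 + B)
    }
    q <- stats::p.adjust(pEmp, method = "BH")
    keep <- q <= params$fdrAlpha
    if (!any(keep)) return(emptySet())

    kept <- runs[keep]
    keptGr <- GRanges(chrom[vapply(kept, `[`, integer(1), 1)],
                      IRanges(start(rr)[vapply(kept, `[`, integer(1), 1)],
                              end(rr)[vapply(kept, function(i)
                                  i[length(i)], integer(1))]))
    mcols(keptGr)$stat <- stat[keep]
    mcols(keptGr)$empirical_p <- pEmp[keep]
    mcols(keptGr)$fdr_q <- q[keep]
    merged <- GenomicRanges::reduce(keptGr,
                                    min.gapwidth = params$mergeDistanceBp)
    ov <- findOverlaps(merged, keptGr)
    aggMin <- function(x) vapply(split(x[subjectHits(ov)], queryHits(ov)),
                                 min, numeric(1))
    probeHits <- findOverlaps(merged, rr)
    probeIds <- split(names(rr)[subjectHits(probeHits)],
                      factor(queryHits(probeHits),
                             levels = seq_along(merged)))
    cpgSum <- vapply(split(mcols(rr)$cpg_count[subjectHits(probeHits)],
                           factor(queryHits(probeHits),
                                  levels = seq_along(merged))),
                     sum, numeric(1))
    statAgg <- vapply(split(stat[keep][subjectHits(ov)], queryHits(ov)),
                      mean, numeric(1))

    names(merged) <- sprintf("DMR%05d", seq_along(merged))
    mcols(merged) <- DataFrame(
        n_probes = lengths(probeIds),
        probe_ids = IRanges::CharacterList(probeIds),
        stat = statAgg,
        empirical_p = aggMin(mcols(keptGr)$empirical_p),
        fdr_q = aggMin(mcols(keptGr)$fdr_q),
        cpg_per_bp = cpgSum / width(merged))
    means <- summarizeDmrs(pm, merged)
    DMRSet(merged, means)
}

#' Per-DMR, per-sample mean probe scores
#'
#' @param pm a [ProbeMatrix-class].
#' @param regions [GenomicRanges::GRanges] (named) or a [DMRSet-class]; the
#'   mean is the arithmetic mean of member-probe scores.
#' @return matrix, regions (genomic order) x samples.
#' @export
summarizeDmrs <- function(pm, regions) {
    if (is(regions, "DMRSet")) regions <- rowRanges(regions)
    ord <- order(as.integer(seqnames(regions)), start(regions))
    regions <- regions[ord]
    hits <- findOverlaps(regions, rowRanges(pm))
    miss <- setdiff(seq_along(regions), unique(queryHits(hits)))
    if (length(miss) > 0) {
        id <- if (!is.null(names(regions))) names(regions)[miss[1]]
              else miss[1]
        stop("no probes found for DMR ", id)
    }
    sc <- probeScores(pm)
    groups <- factor(queryHits(hits), levels = seq_along(regions))
    sums <- rowsum(sc[subjectHits(hits), , drop = FALSE], groups)
    out <- sums / as.integer(table(groups))
    rownames(out) <- if (!is.null(names(regions))) names(regions)
                     else as.character(seq_along(regions))
    out
}
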