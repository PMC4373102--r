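## Basewise annotation of DMRs against interval tracks: overlap counting,
## consensus chromatin states, aggregation profiles, transition matrices,
## repeat and chromosome-end features, and enrichment statistics.

.trackLabels <- function(track) {
    mc <- mcols(track)
    if ("state" %in% colnames(mc)) as.character(mc$state)
    else if ("label" %in% colnames(mc)) as.character(mc$label)
    else rep("track", length(track))
}

#' Basewise overlap of intervals with a labelled track
#'
#' Counts, for every query interval, the exact number of bases covered by
#' track intervals of each label (the `state` or `label` metadata column; a
#' single pseudo-label `"track"` for unlabelled tracks). Query intervals on
#' chromosomes absent from the track count zero bases, with a warning.
#'
#' @param intervals query [GenomicRanges::GRanges].
#' @param track labelled track [GenomicRanges::GRanges].
#' @return integer matrix, intervals x labels.
#' @export
basewiseOverlap <- function(intervals, track) {
    labels <- .trackLabels(track)
    labelLevels <- sort(unique(labels))
    out <- matrix(0L, length(intervals), length(labelLevels),
                  dimnames = list(names(intervals), labelLevels))
    if (length(intervals) == 0 || length(track) == 0) return(out)
    unknown <- !as.character(seqnames(intervals)) %in%
        unique(as.character(seqnames(track)))
    if (any(unknown))
        warning(sum(unknown), " interval(s) on chromosomes absent from ",
                "the track count as 0")
    for (lab in labelLevels) {
        sub <- GenomicRanges::reduce(track[labels == lab])
        suppressWarnings(hits <- findOverlaps(intervals, sub))
        if (length(hits) == 0) next
        w <- width(pintersect(intervals[queryHits(hits)],
                              sub[subjectHits(hits)]))
        agg <- rowsum(w, queryHits(hits))
        out[as.integer(rownames(agg)), lab] <- as.integer(agg)
    }
    out
}

#' Consensus label by basewise majority vote
#'
#' @param counts matrix of base counts (rows = intervals, columns = labels,
#'   e.g. from [basewiseOverlap()]).
#' @return per-row winning label; ties go to the lowest label (numeric
#'   order when labels are numbers).
#' @export
consensusState <- function(counts) {
    labs <- colnames(counts)
    num <- suppressWarnings(as.numeric(labs))
    ord <- if (!anyNA(num)) order(num) else order(labs)
    counts <- counts[, ord, drop = FALSE]
    win <- max.col(counts, ties.method = "first")
    out <- colnames(counts)[win]
    num2 <- suppressWarnings(as.numeric(out))
    if (!anyNA(num2)) out <- as.integer(num2)
    stats::setNames(out, rownames(counts))
}

#' Per-base aggregation profile across windows centered on anchors
#'
#' For each anchor (interval midpoint, or TSS when `orientation =
#' "strand"`), a window of `windowBp` bases is laid out and the track's
#' basewise occupancy recorded; minus-strand anchors are flipped so
#' downstream is always to the right. The aggregate frequency at each
#' window position divides by the number of anchors whose window covers
#' that position (windows truncate at chromosome edges).
#'
#' @param anchors [GenomicRanges::GRanges]; midpoints are used.
#' @param track occupancy [GenomicRanges::GRanges].
#' @param windowBp even window width, bp.
#' @param orientation `"none"` (unoriented midpoints) or `"strand"` (flip
#'   minus-strand anchors).
#' @param chromLens named chromosome lengths for edge truncation; inferred
#'   from the track when missing.
#' @return An [AggregationProfile-class].
#' @export
windowProfile <- function(anchors, track, windowBp = 4000L,
                          orientation = c("none", "strand"),
                          chromLens = NULL) {
    orientation <- match.arg(orientation)
    windowBp <- as.integer(windowBp)
    if (windowBp <= 0 || windowBp %% 2L != 0L)
        stop("windowBp must be a positive even integer")
    half <- windowBp %/% 2L
    mid <- floor((start(anchors) + end(anchors)) / 2)
    chrom <- as.character(seqnames(anchors))
    if (is.null(chromLens)) {
        trackMax <- tapply(end(track), as.character(seqnames(track)), max)
        chromLens <- stats::setNames(as.numeric(trackMax), names(trackMax))
    }
    rows <- matrix(NA_real_, length(anchors), windowBp)
    rownames(rows) <- names(anchors)
    trk <- GenomicRanges::reduce(track)
    for (i in seq_along(anchors)) {
        lo <- mid[i] - half            # window positions lo .. lo+w-1
        positions <- lo + 0:(windowBp - 1L)
        lim <- chromLens[chrom[i]]
        valid <- positions >= 1 & (!is.na(lim) & positions <= lim)
        occ <- rep(0, windowBp)
        sub <- trk[as.character(seqnames(trk)) == chrom[i] &
                       end(trk) >= lo & start(trk) <= lo + windowBp - 1L]
        for (j in seq_along(sub)) {
            a <- max(start(sub)[j], lo) - lo + 1L
            b <- min(end(sub)[j], lo + windowBp - 1L) - lo + 1L
            occ[a:b] <- 1
        }
        occ[!valid] <- NA_real_
        if (orientation == "strand" &&
            as.character(strand(anchors)[i]) == "-")
            occ <- rev(occ)
        rows[i, ] <- occ
    }
    freq <- colMeans(rows, na.rm = TRUE)
    freq[is.nan(freq)] <- 0
    new("AggregationProfile", window = windowBp, frequency = freq,
        anchorCount = length(anchors), anchorRows = rows,
        sortKey = rowSums(rows, na.rm = TRUE))
}

#' Chromatin-state transition frequencies across cell lines
#'
#' Given per-DMR consensus states for a reference cell line and one or more
#' alternate cell lines, returns, for each alternate cell line, the
#' frequency distribution of alternate states among DMRs sharing each
#' reference state (rows sum to 1 over alternate states).
#'
#' @param states matrix of consensus states, DMRs x cell lines.
#' @param refCell column name of the reference cell line.
#' @param restrictTo optional single reference state to restrict rows to.
#' @return named list (one row-stochastic matrix per alternate cell line).
#' @export
transitionMatrix <- function(states, refCell, restrictTo = NULL) {
    stopifnot(refCell %in% colnames(states))
    ref <- states[, refCell]
    alts <- setdiff(colnames(states), refCell)
    refLevels <- sort(unique(ref))
    if (!is.null(restrictTo)) refLevels <- restrictTo
    out <- list()
    for (cell in alts) {
        tab <- matrix(0, length(refLevels), 15,
                      dimnames = list(refLevels, 1:15))
        for (s in refLevels) {
            alt <- states[ref == s, cell]
            if (length(alt) == 0) next
            tab[as.character(s), ] <- tabulate(as.integer(alt), 15) /
                length(alt)
        }
        out[[cell]] <- tab
    }
    out
}

#' Local repeat content around DMR midpoints
#'
#' Basewise overlap of repeat intervals with the fixed window centered on
#' each DMR midpoint, plus a presence flag.
#'
#' @param dmrs [GenomicRanges::GRanges].
#' @param repeatTrack repeat intervals.
#' @param window window width, bp (default 2 kb).
#' @return data.frame with `bases` and `present`.
#' @export
repeatContent <- function(dmrs, repeatTrack, window = 2000L) {
    half <- as.integer(window) %/% 2L
    mid <- floor((start(dmrs) + end(dmrs)) / 2)
    win <- GRanges(seqnames(dmrs),
                   IRanges(pmax(mid - half, 1), mid + half - 1L))
    rep_ <- GenomicRanges::reduce(repeatTrack)
    counts <- basewiseOverlap(win, rep_)
    bases <- as.integer(rowSums(counts))
    data.frame(dmr = if (is.null(names(dmrs)))
        as.character(seq_along(dmrs)) else names(dmrs),
        bases = bases, present = bases > 0, row.names = NULL)
}

#' Distance to the nearest chromosome end and subtelomere flag
#'
#' @param dmrs [GenomicRanges::GRanges].
#' @param chromLengths named chromosome sizes, bp.
#' @param subtelomereBp flag threshold (default 5 Mb).
#' @return data.frame with `distance` (bp, 0 at the very end) and
#'   `subtelomeric`.
#' @export
chromEndFeatures <- function(dmrs, chromLengths, subtelomereBp = 5e6) {
    L <- chromLengths[as.character(seqnames(dmrs))]
    if (anyNA(L)) stop("chromosome missing from chromLengths")
    d <- pmin(start(dmrs) - 1, L - end(dmrs))
    data.frame(dmr = if (is.null(names(dmrs)))
        as.character(seq_along(dmrs)) else names(dmrs),
        distance = as.numeric(d), subtelomeric = d <= subtelomereBp,
        row.names = NULL)
}

#' Feature enrichment across groups
#'
#' Boolean features: one-vs-rest two-sided Fisher test per group (odds
#' ratio and p). Continuous features: Mann-Whitney for two groups,
#' Kruskal-Wallis for three or more (tie-corrected).
#'
#' @param feature logical or numeric vector per item.
#' @param group group label per item.
#' @return for boolean features a data.frame (group, counts, odds ratio,
#'   p, direction); for continuous features a list with `test`,
#'   `statistic`, `p`.
#' @export
categoryEnrichment <- function(feature, group) {
    group <- as.factor(group)
    if (is.logical(feature)) {
        out <- lapply(levels(group), function(g) {
            a <- sum(feature & group == g)
            b <- sum(!feature & group == g)
            c_ <- sum(feature & group != g)
            d <- sum(!feature & group != g)
            ft <- fisher2x2(a, b, c_, d)
            data.frame(group = g, n_in = a + b, feature_in = a,
                       feature_out = c_, odds_ratio = ft$odds_ratio,
                       p = ft$p,
                       direction = ifelse(ft$odds_ratio > 1, "enriched",
                                          ifelse(ft$odds_ratio < 1,
                                                 "depleted", "none")))
        })
        do.call(rbind, out)
    } else {
        if (nlevels(group) == 2) {
            ht <- stats::wilcox.test(feature ~ group)
            list(test = "mann-whitney", statistic = unname(ht$statistic),
                 p = ht$p.value)
        } else {
            ht <- stats::kruskal.test(feature ~ group)
            list(test = "kruskal-wallis", statistic = unname(ht$statistic),
                 p = ht$p.value)
        }
    }
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric overlap test of a gene list against each
#' signature set within a universe, Benjamini-Hochberg corrected across
#' sets.
#'
#' @param genes character vector of hit genes.
#' @param signatures named list of signature gene sets.
#' @param universe character vector of all eligible genes.
#' @return data.frame with set, overlap, setSize, p, q.
#' @export
genesetOverlap <- function(genes, signatures, universe) {
    genes <- intersect(unique(genes), universe)
    k <- length(genes)
    N <- length(universe)
    res <- lapply(names(signatures), function(nm) {
        sig <- intersect(unique(signatures[[nm]]), universe)
        m <- length(sig)
        q <- length(intersect(genes, sig))
        p <- stats::phyper(q - 1, m, N - m, k, lower.tail = FALSE)
        data.frame(set = nm, overlap = q, setSize = m, p = p)
    })
    res <- do.call(rbind, res)
    res$q <- stats::p.adjust(res$p, method = "BH")
    res
}

#' Assemble per-DMR context features
#'
#' Convenience wrapper computing CpG density, CGI and 2-kb-flank shore
#' overlap, conserved-element bases, per-cell consensus chromatin states,
#' local repeat content and chromosome-end features from a
#' [GenomeTracks-class] bundle.
#'
#' @param dmrs [DMRSet-class] or named [GenomicRanges::GRanges].
#' @param tracks a [GenomeTracks-class].
#' @param shoreFlankBp CGI shore flank width (default 2 kb).
#' @return data.frame of per-DMR features plus a `consensus_state.<cell>`
#'   column per segmentation track.
#' @export
contextFeatures <- function(dmrs, tracks, shoreFlankBp = 2000L) {
    gr <- if (is(dmrs, "DMRSet")) rowRanges(dmrs) else dmrs
    cgi <- getTrack(tracks, "cgi")
    shores <- GenomicRanges::setdiff(
        GenomicRanges::reduce(gr_expand(cgi, shoreFlankBp)), cgi)
    out <- data.frame(
        dmr = names(gr),
        cgi_overlap = overlapsAny(gr, cgi),
        shore_overlap = overlapsAny(gr, shores),
        row.names = NULL)
    if ("ncec" %in% trackNames(tracks))
        out$ncec_bases <- as.integer(rowSums(
            basewiseOverlap(gr, getTrack(tracks, "ncec"))))
    segs <- grep("^states\\.", trackNames(tracks), value = TRUE)
    for (s in segs) {
        counts <- basewiseOverlap(gr, getTrack(tracks, s))
        out[[paste0("consensus_state.", sub("^states\\.", "", s))]] <-
            consensusState(counts)
    }
    if ("repeats" %in% trackNames(tracks)) {
        rc <- repeatContent(gr, getTrack(tracks, "repeats"))
        out$repeat_bases_2kb <- rc$bases
        out$repeat_present <- rc$present
    }
    ce <- chromEndFeatures(gr, chromLengths(tracks))
    out$dist_to_chrom_end <- ce$distance
    out$subtelomeric <- ce$subtelomeric
    out
}

# expand ranges by a flank on both sides, clipped at 1
gr_expand <- function(gr, flank) {
    GRanges(seqnames(gr),
            IRanges(pmax(start(gr) - flank, 1), end(gr) + flank))
}
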