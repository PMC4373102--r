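#' Construct a simulation configuration
#'
#' @param nPerSubgroup tumor samples per subgroup (four integers).
#' @param nNormals number of normal samples.
#' @param nDmrsPerPattern planted DMRs per methylation pattern (three
#'   integers). The full-cohort default is c(672, 650, 1375); pass a
#'   scaled-down vector for quick runs.
#' @param nNullProbes number of background probes.
#' @param probeSpacing probe footprint and tiling step, bp.
#' @param chromLengths named chromosome sizes, bp.
#' @param effectSize score separation between methylated and unmethylated
#'   DMR states.
#' @param noiseSd per-probe Gaussian noise SD.
#' @param cpgDensity named CpG-per-bp densities for
#'   pattern1/pattern2/pattern3/background probes.
#' @param exprCorrFraction fraction of pattern-3 DMRs with planted negative
#'   expression correlation.
#' @param exprCorrTarget magnitude of the planted correlation.
#' @param seed RNG seed.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nDmrsPerPattern = c(10, 10, 20), nNullProbes = 500)
#' cfg
#' @export
simConfig <- function(nPerSubgroup = c(18L, 21L, 24L, 35L),
                      nNormals = 4L,
                      nDmrsPerPattern = c(672L, 650L, 1375L),
                      nNullProbes = 50000L,
                      probeSpacing = 100L,
                      chromLengths = c(chr1 = 30e6, chr2 = 30e6, chr3 = 30e6),
                      effectSize = 2.5,
                      noiseSd = 0.5,
                      cpgDensity = c(pattern1 = 0.014, pattern2 = 0.048,
                                     pattern3 = 0.022, background = 0.011),
                      exprCorrFraction = 0.3,
                      exprCorrTarget = 0.8,
                      seed = 1L) {
    new("SimConfig",
        nPerSubgroup = as.integer(nPerSubgroup),
        nNormals = as.integer(nNormals),
        nDmrsPerPattern = as.integer(nDmrsPerPattern),
        nNullProbes = as.integer(nNullProbes),
        probeSpacing = as.integer(probeSpacing),
        chromLengths = chromLengths,
        effectSize = effectSize,
        noiseSd = noiseSd,
        cpgDensity = cpgDensity,
        exprCorrFraction = exprCorrFraction,
        exprCorrTarget = exprCorrTarget,
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:",
        sum(object@nPerSubgroup), "tumors (",
        paste(object@nPerSubgroup, collapse = "/"), ") +",
        object@nNormals, "normals;",
        paste(object@nDmrsPerPattern, collapse = "/"),
        "DMRs per pattern;", object@nNullProbes, "null probes\n")
    cat("  genome:", paste(names(object@chromLengths), collapse = ","),
        "| effect", object@effectSize, "| noise SD", object@noiseSd,
        "| seed", object@seed, "\n")
})

#' Construct a probe-level methylation matrix
#'
#' @param ranges [GenomicRanges::GRanges] of probe footprints, named by
#'   probe id, with a `cpg_count` metadata column.
#' @param score numeric matrix, probes x samples.
#' @param colData optional per-sample annotation ([S4Vectors::DataFrame]).
#' @return A [ProbeMatrix-class].
#' @export
ProbeMatrix <- function(ranges, score, colData = NULL) {
    score <- as.matrix(score)
    rownames(score) <- names(ranges)
    if (is.null(colnames(score)))
        colnames(score) <- sprintf("S%03d", seq_len(ncol(score)))
    if (is.null(colData))
        colData <- DataFrame(row.names = colnames(score))
    ord <- order(as.integer(seqnames(ranges)), start(ranges))
    new("ProbeMatrix", SummarizedExperiment(
        assays = list(score = score[ord, , drop = FALSE]),
        rowRanges = ranges[ord], colData = colData))
}

#' @rdname ProbeMatrix
#' @param x a `ProbeMatrix`.
#' @export
probeScores <- function(x) assay(x, "score")

#' @rdname ProbeMatrix
#' @export
probeCpG <- function(x) setNames(rowData(x)$cpg_count, rownames(x))

setMethod("show", "ProbeMatrix", function(object) {
    cat("ProbeMatrix:", nrow(object), "probes x", ncol(object), "samples on",
        length(unique(as.character(seqnames(rowRanges(object))))),
        "chromosome(s)\n")
    cat("  score range:",
        paste(signif(range(assay(object, "score")), 3), collapse = " .. "),
        "| CpG/probe median:", stats::median(rowData(object)$cpg_count), "\n")
})

#' Construct a DMR set
#'
#' @param ranges [GenomicRanges::GRanges] of DMR intervals (named by DMR id).
#' @param meanScore numeric matrix of per-DMR per-sample mean scores.
#' @param rowData optional extra per-DMR annotation.
#' @return A [DMRSet-class].
#' @export
DMRSet <- function(ranges, meanScore, rowData = NULL) {
    meanScore <- as.matrix(meanScore)
    rownames(meanScore) <- names(ranges)
    if (!is.null(rowData))
        mcols(ranges) <- cbind(mcols(ranges), rowData)
    ord <- order(as.integer(seqnames(ranges)), start(ranges))
    new("DMRSet", SummarizedExperiment(
        assays = list(meanScore = meanScore[ord, , drop = FALSE]),
        rowRanges = ranges[ord]))
}

#' @rdname DMRSet
#' @param x a `DMRSet`.
#' @export
dmrMeans <- function(x) assay(x, "meanScore")

#' @rdname DMRSet
#' @export
dmrPattern <- function(x) {
    p <- rowData(x)$pattern
    if (is.null(p)) rep(NA_integer_, nrow(x)) else p
}

#' @rdname DMRSet
#' @param value integer pattern labels (1-3) or NA.
#' @export
`dmrPattern<-` <- function(x, value) {
    rowData(x)$pattern <- as.integer(value)
    x
}

setMethod("show", "DMRSet", function(object) {
    cat("DMRSet:", nrow(object), "DMRs x", ncol(object), "samples\n")
    if (nrow(object)) {
        cat("  width:", paste(range(width(rowRanges(object))), collapse = " .. "),
            "bp | median", stats::median(width(rowRanges(object))), "bp\n")
        p <- dmrPattern(object)
        if (!all(is.na(p)))
            cat("  patterns:",
                paste(sprintf("%d:%d", 1:3, tabulate(p, 3L)), collapse = " "),
                "\n")
    }
})

#' Construct a genome-track collection
#'
#' @param tracks named list of [GenomicRanges::GRanges].
#' @param chromLengths named chromosome sizes (bp).
#' @param geneModels [GenomicRanges::GRanges] of TSS positions with
#'   `gene_id`; defaults to empty.
#' @return A [GenomeTracks-class].
#' @export
GenomeTracks <- function(tracks = list(), chromLengths,
                         geneModels = GRanges(gene_id = character())) {
    new("GenomeTracks", tracks = tracks, chromLengths = chromLengths,
        geneModels = geneModels)
}

#' @rdname GenomeTracks
#' @param x a `GenomeTracks`.
#' @param name track name; omit to get the full named list.
#' @export
getTrack <- function(x, name) {
    if (missing(name)) return(x@tracks)
    if (!name %in% names(x@tracks))
        stop("unknown track: ", name)
    x@tracks[[name]]
}

#' @rdname GenomeTracks
#' @export
trackNames <- function(x) names(x@tracks)

#' @rdname GenomeTracks
#' @export
chromLengths <- function(x) x@chromLengths

#' @rdname GenomeTracks
#' @export
geneModels <- function(x) x@geneModels

setMethod("show", "GenomeTracks", function(object) {
    cat("GenomeTracks:", length(object@tracks), "tracks on",
        length(object@chromLengths), "chromosomes;",
        length(object@geneModels), "gene models\n")
    if (length(object@tracks))
        cat("  ", paste(utils::head(names(object@tracks), 8), collapse = ", "),
            if (length(object@tracks) > 8) "..." else "", "\n")
})

#' Construct an ordered locus model
#'
#' @param dmrIds ordered DMR ids, genomic 5' to 3'.
#' @param boundary last index belonging to the anterior block.
#' @param locusName display name.
#' @return A [LocusModel-class].
#' @export
locusModel <- function(dmrIds, boundary, locusName = "locus") {
    new("LocusModel", dmrIds = as.character(dmrIds),
        boundary = as.integer(boundary), locusName = locusName)
}

setMethod("show", "LocusModel", function(object) {
    cat("LocusModel '", object@locusName, "': ", length(object@dmrIds),
        " DMRs, anterior block 1..", object@boundary, "\n", sep = "")
})

setMethod("show", "AggregationProfile", function(object) {
    cat("AggregationProfile:", object@window, "bp window,",
        object@anchorCount, "anchors; mean occupancy",
        signif(mean(object@frequency), 3), "\n")
})

#' @rdname AggregationProfile-class
#' @param x an `AggregationProfile`.
#' @export
profileFrequency <- function(x) x@frequency

#' @rdname AggregationProfile-class
#' @export
profileRows <- function(x) x@anchorRows[order(-x@sortKey), , drop = FALSE]
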