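#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- queryHits subjectHits
#' @import IRanges
#' @import GenomicRanges
#' @import SummarizedExperiment
NULL

#' Simulation configuration for the synthetic tumor cohort
#'
#' Holds every knob of the synthetic-data generator. Defaults encode the
#' study conditions the pipeline targets: four tumor subgroups of
#' 18/21/24/35 samples plus 4 normal urothelium samples, three DMR
#' methylation patterns of 672/650/1375 regions, a three-chromosome
#' 30-Mb-per-chromosome genome, and per-pattern CpG densities of
#' 0.014/0.048/0.022 CpG per bp (background 0.011).
#'
#' @slot nPerSubgroup integer(4), tumor samples per subgroup.
#' @slot nNormals integer(1), normal samples.
#' @slot nDmrsPerPattern integer(3), planted DMRs per methylation pattern.
#' @slot nNullProbes integer(1), background probes carrying noise only.
#' @slot probeSpacing integer(1), probe footprint/tiling step in bp.
#' @slot chromLengths named numeric, chromosome sizes in bp.
#' @slot effectSize numeric(1), score separation of methylated vs
#'   unmethylated DMR states (log-ratio units).
#' @slot noiseSd numeric(1), per-probe Gaussian noise SD.
#' @slot cpgDensity named numeric(4) (`pattern1`, `pattern2`, `pattern3`,
#'   `background`), CpG per bp used to draw per-probe CpG counts.
#' @slot exprCorrFraction numeric(1), fraction of pattern-3 DMRs given
#'   negatively correlated expression.
#' @slot exprCorrTarget numeric(1), magnitude of the planted methylation to
#'   expression correlation.
#' @slot seed integer(1), RNG seed; identical config implies byte-identical
#'   output.
#' @export
setClass("SimConfig", representation(
    nPerSubgroup     = "integer",
    nNormals         = "integer",
    nDmrsPerPattern  = "integer",
    nNullProbes      = "integer",
    probeSpacing     = "integer",
    chromLengths     = "numeric",
    effectSize       = "numeric",
    noiseSd          = "numeric",
    cpgDensity       = "numeric",
    exprCorrFraction = "numeric",
    exprCorrTarget   = "numeric",
    seed             = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- NULL
    if (length(object@nPerSubgroup) != 4L || any(object@nPerSubgroup < 1L))
        msg <- c(msg, "nPerSubgroup must be four positive integers")
    if (object@nNormals < 0L)
        msg <- c(msg, "nNormals must be non-negative")
    if (length(object@nDmrsPerPattern) != 3L || any(object@nDmrsPerPattern < 1L))
        msg <- c(msg, "nDmrsPerPattern must be three positive integers")
    if (object@nNullProbes < 0L)
        msg <- c(msg, "nNullProbes must be non-negative")
    if (object@probeSpacing < 1L)
        msg <- c(msg, "probeSpacing must be positive")
    if (is.null(names(object@chromLengths)) || any(object@chromLengths <= 0))
        msg <- c(msg, "chromLengths must be a named vector of positive sizes")
    if (object@effectSize <= 0)
        msg <- c(msg, "effectSize must be > 0")
    if (object@noiseSd < 0)
        msg <- c(msg, "noiseSd must be >= 0")
    dens <- object@cpgDensity
    if (!all(c("pattern1", "pattern2", "pattern3", "background") %in% names(dens)) ||
        any(dens < 0))
        msg <- c(msg, "cpgDensity must name pattern1/pattern2/pattern3/background, all >= 0")
    if (object@exprCorrFraction < 0 || object@exprCorrFraction > 1)
        msg <- c(msg, "exprCorrFraction must lie in [0, 1]")
    if (object@exprCorrTarget <= 0 || object@exprCorrTarget > 1)
        msg <- c(msg, "exprCorrTarget must lie in (0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Ground truth of a simulated cohort
#'
#' Records what the generator planted so recovery can be scored: DMR
#' intervals with their methylation pattern, per-sample subgroup labels, and
#' the DMR-gene pairs given planted expression correlation.
#'
#' @slot dmrRanges [GenomicRanges::GRanges] of planted DMRs; `mcols` carry
#'   `dmr_id` and `pattern` (1, 2 or 3).
#' @slot subgroups named integer, subgroup (1-4) per tumor sample; 0 marks
#'   normal samples.
#' @slot exprPairs data.frame with columns `dmr_id`, `gene_id`, `sign` for
#'   planted methylation-expression correlations.
#' @export
setClass("SyntheticTruth", representation(
    dmrRanges = "GRanges",
    subgroups = "integer",
    exprPairs = "data.frame"
))

setValidity("SyntheticTruth", function(object) {
    msg <- NULL
    if (is.null(names(object@subgroups)))
        msg <- c(msg, "subgroups must be named by sample id")
    if (!all(c("dmr_id", "pattern") %in% colnames(mcols(object@dmrRanges))))
        msg <- c(msg, "dmrRanges must carry dmr_id and pattern metadata")
    if (is.null(msg)) TRUE else msg
})

#' Probe-level methylation score matrix
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are array
#' probes (genomic footprint plus per-probe CpG count in
#' `rowData()$cpg_count`) and whose single assay `"score"` holds normalized
#' methylation-enrichment log-ratios, probes x samples. Rows are kept sorted
#' by (chromosome, start); probe ids are unique.
#'
#' @export
setClass("ProbeMatrix", contains = "RangedSummarizedExperiment")

setValidity("ProbeMatrix", function(object) {
    msg <- NULL
    if (!"score" %in% assayNames(object))
        msg <- c(msg, "assay 'score' is required")
    rr <- rowRanges(object)
    if (is.null(names(rr)) || anyDuplicated(names(rr)))
        msg <- c(msg, "probe ids (rownames) must be present and unique")
    if (!"cpg_count" %in% colnames(mcols(rr)))
        msg <- c(msg, "rowData must carry cpg_count")
    else if (any(mcols(rr)$cpg_count < 0))
        msg <- c(msg, "cpg_count must be >= 0")
    if (any(width(rr) < 1))
        msg <- c(msg, "probe end must exceed start")
    if (is.unsorted(order(as.integer(seqnames(rr)), start(rr))) ||
        !identical(order(as.integer(seqnames(rr)), start(rr)), seq_along(rr)))
        msg <- c(msg, "probes must be sorted by (chrom, start)")
    if (length(msg) == 0 && anyNA(assay(object, "score")))
        msg <- c(msg, "scores must not contain missing values")
    if (is.null(msg)) TRUE else msg
})

#' Set of called differentially methylated regions
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are DMR
#' intervals in genomic order and whose assay `"meanScore"` holds the
#' per-DMR, per-sample mean of member-probe scores. `rowData()` carries
#' `n_probes`, `probe_ids` (CharacterList), `cpg_per_bp`, `stat`,
#' `empirical_p`, `fdr_q`, and (once assigned) `pattern`.
#'
#' @export
setClass("DMRSet", contains = "RangedSummarizedExperiment")

setValidity("DMRSet", function(object) {
    msg <- NULL
    if (!"meanScore" %in% assayNames(object))
        msg <- c(msg, "assay 'meanScore' is required")
    if (length(object) > 1) {
        rr <- rowRanges(object)
        hits <- findOverlaps(rr, drop.self = TRUE, drop.redundant = TRUE)
        if (length(hits) > 0)
            msg <- c(msg, "DMRs must be non-overlapping")
    }
    if (is.null(msg)) TRUE else msg
})

#' Named collection of genome annotation tracks
#'
#' Bundles the interval tracks a DMR landscape is annotated against: CpG
#' islands, per-cell-line 15-state chromatin segmentations, regulatory-factor
#' ChIP-seq peaks, DNase hypersensitive sites, repeats and conserved
#' elements, together with chromosome lengths and gene TSS models.
#'
#' @slot tracks named list of [GenomicRanges::GRanges]; segmentation tracks
#'   carry an integer `state` column (1-15), peak tracks are named
#'   `"<RF>.<cell>"`.
#' @slot chromLengths named numeric of chromosome sizes (bp).
#' @slot geneModels [GenomicRanges::GRanges] of width-1 TSS positions with
#'   `gene_id` metadata and strand.
#' @export
setClass("GenomeTracks", representation(
    tracks       = "list",
    chromLengths = "numeric",
    geneModels   = "GRanges"
))

setValidity("GenomeTracks", function(object) {
    msg <- NULL
    if (length(object@tracks) && is.null(names(object@tracks)))
        msg <- c(msg, "tracks must be named")
    for (nm in names(object@tracks)) {
        gr <- object@tracks[[nm]]
        if (!is(gr, "GRanges")) {
            msg <- c(msg, sprintf("track '%s' is not a GRanges", nm))
            next
        }
        bad <- !as.character(seqnames(gr)) %in% names(object@chromLengths)
        if (any(bad)) {
            msg <- c(msg, sprintf("track '%s' uses unknown chromosomes", nm))
            next
        }
        if (any(start(gr) < 1) ||
            any(end(gr) > object@chromLengths[as.character(seqnames(gr))]))
            msg <- c(msg, sprintf("track '%s' exceeds chromosome bounds", nm))
        if ("state" %in% colnames(mcols(gr))) {
            st <- mcols(gr)$state
            if (any(is.na(st)) || any(st < 1L) || any(st > 15L))
                msg <- c(msg, sprintf("track '%s' has states outside 1..15", nm))
            if (length(findOverlaps(gr, drop.self = TRUE,
                                    drop.redundant = TRUE)) > 0)
                msg <- c(msg, sprintf("segmentation '%s' has overlapping segments", nm))
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Per-base occupancy profile around a set of anchors
#'
#' Aggregates a track over fixed windows centered on anchors (DMR midpoints
#' or TSSs): `frequency[i]` is the fraction of anchors whose window position
#' i (1-based, window start at -window/2) is covered by the track. Per-anchor
#' basewise rows are retained for heat-strip export, with a sort key equal to
#' the number of occupied bases per anchor.
#'
#' @slot window integer window width in bp (even).
#' @slot frequency numeric of length `window`, values in [0, 1].
#' @slot anchorCount integer, number of anchors aggregated.
#' @slot anchorRows 0/1 matrix, anchors x window positions.
#' @slot sortKey numeric, occupied bases per anchor.
#' @export
setClass("AggregationProfile", representation(
    window      = "integer",
    frequency   = "numeric",
    anchorCount = "integer",
    anchorRows  = "matrix",
    sortKey     = "numeric"
))

setValidity("AggregationProfile", function(object) {
    msg <- NULL
    if (length(object@frequency) != object@window)
        msg <- c(msg, "frequency length must equal window")
    if (any(object@frequency < 0 | object@frequency > 1, na.rm = TRUE))
        msg <- c(msg, "frequencies must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Ordered locus model for switch classification
#'
#' An ordered DMR list (genomic 5' to 3') with a boundary index splitting an
#' anterior block (ids 1..boundary) from a posterior block.
#'
#' @slot dmrIds character, ordered DMR ids.
#' @slot boundary integer, last index of the anterior block.
#' @slot locusName character.
#' @export
setClass("LocusModel", representation(
    dmrIds   = "character",
    boundary = "integer",
    locusName = "character"
))

setValidity("LocusModel", function(object) {
    msg <- NULL
    if (object@boundary < 1L || object@boundary >= length(object@dmrIds))
        msg <- c(msg, "boundary must split the DMR list into two non-empty blocks")
    if (anyDuplicated(object@dmrIds))
        msg <- c(msg, "DMR ids must be unique")
    if (is.null(msg)) TRUE else msg
})
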