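## Regulatory-factor occupancy: binary DMR x (RF, cell line) overlap
## matrix, co-binding definitions, pattern-wise enrichment, and clustering
## of the binary matrix.

#' Binary DMR x (RF, cell line) peak-overlap matrix
#'
#' Entry 1 iff the DMR overlaps (>= 1 bp) any peak of that (RF, cell)
#' track. Track names follow `"<RF>.<cell>"` (an optional `"rf."` prefix is
#' stripped). When `rfs`/`cells` are declared, a missing (RF, cell) track
#' is an error.
#'
#' @param dmrs [DMRSet-class] or named [GenomicRanges::GRanges].
#' @param peaks named list of peak [GenomicRanges::GRanges], or a
#'   [GenomeTracks-class] (its `rf.*` tracks are used).
#' @param rfs,cells optional declared core sets.
#' @return binary integer matrix with column metadata in
#'   `attr(, "columns")` (data.frame rf, cell).
#' @export
buildRfMatrix <- function(dmrs, peaks, rfs = NULL, cells = NULL) {
    gr <- if (is(dmrs, "DMRSet")) rowRanges(dmrs) else dmrs
    if (is(peaks, "GenomeTracks")) {
        nm <- grep("^rf\\.", trackNames(peaks), value = TRUE)
        peaks <- stats::setNames(lapply(nm, getTrack, x = peaks),
                                 sub("^rf\\.", "", nm))
    }
    parts <- strsplit(names(peaks), ".", fixed = TRUE)
    info <- data.frame(rf = vapply(parts, `[`, character(1), 1),
                       cell = vapply(parts, function(p)
                           paste(p[-1], collapse = "."), character(1)))
    if (!is.null(rfs) && !is.null(cells)) {
        want <- expand.grid(rf = rfs, cell = cells,
                            stringsAsFactors = FALSE)
        have <- paste(info$rf, info$cell)
        missing_ <- setdiff(paste(want$rf, want$cell), have)
        if (length(missing_) > 0)
            stop("missing peak track(s): ",
                 paste(missing_, collapse = ", "))
        keep <- have %in% paste(want$rf, want$cell)
        peaks <- peaks[keep]; info <- info[keep, , drop = FALSE]
    }
    m <- vapply(peaks, function(p)
        as.integer(suppressWarnings(overlapsAny(gr, p))),
        integer(length(gr)))
    if (length(gr) == 1L) m <- matrix(m, nrow = 1)
    dimnames(m) <- list(names(gr), names(peaks))
    attr(m, "columns") <- info
    m
}

#' Fraction of DMRs with at least one overlapping peak
#'
#' @param rfMatrix matrix from [buildRfMatrix()].
#' @param patterns optional pattern label per DMR for a per-pattern
#'   breakdown.
#' @return list with `overall` and (when patterns given) `byPattern`.
#' @export
rfOverlapFractions <- function(rfMatrix, patterns = NULL) {
    any_ <- rowSums(rfMatrix) > 0
    out <- list(overall = mean(any_))
    if (!is.null(patterns))
        out$byPattern <- tapply(any_, patterns, mean)
    out
}

#' Co-binding of a set of regulatory factors
#'
#' `same_cell`: all named RFs overlap the DMR in at least one common cell
#' line. `all_cells`: the full RF set overlaps in every cell line.
#'
#' @param rfMatrix matrix from [buildRfMatrix()].
#' @param rfs RF names.
#' @param mode `"any_cell_same_cell"` or `"all_cells"`.
#' @return logical per DMR.
#' @export
cobinding <- function(rfMatrix, rfs,
                      mode = c("any_cell_same_cell", "all_cells")) {
    mode <- match.arg(mode)
    info <- attr(rfMatrix, "columns")
    stopifnot(!is.null(info), all(rfs %in% info$rf))
    cells <- unique(info$cell)
    perCell <- vapply(cells, function(cl) {
        cols <- which(info$cell == cl & info$rf %in% rfs)
        if (length(cols) < length(rfs)) return(rep(FALSE, nrow(rfMatrix)))
        rowSums(rfMatrix[, cols, drop = FALSE]) == length(rfs)
    }, logical(nrow(rfMatrix)))
    if (nrow(rfMatrix) == 1L) perCell <- matrix(perCell, nrow = 1)
    if (mode == "any_cell_same_cell") rowSums(perCell) > 0
    else rowSums(perCell) == length(cells)
}

#' Pattern-wise enrichment of a co-binding flag
#'
#' One-vs-rest two-sided Fisher test per methylation pattern, with
#' direction from the odds ratio.
#'
#' @param flags logical co-binding flag per DMR.
#' @param patterns pattern label per DMR.
#' @return data.frame (group, counts, odds_ratio, p, direction).
#' @export
patternRfEnrichment <- function(flags, patterns) {
    categoryEnrichment(as.logical(flags), patterns)
}

#' Cluster the binary RF-occupancy matrix
#'
#' Average-linkage hierarchical clustering of rows and columns on Jaccard
#' distance; leaf ordering is hclust's deterministic ordering (ties resolve
#' to input order), so duplicated columns end up adjacent.
#'
#' @param rfMatrix matrix from [buildRfMatrix()].
#' @return list with `rowOrder`, `colOrder`, `rowHclust`, `colHclust`.
#' @export
clusterRfMatrix <- function(rfMatrix) {
    rh <- stats::hclust(jaccardDist(rfMatrix), method = "average")
    ch <- stats::hclust(jaccardDist(t(rfMatrix)), method = "average")
    list(rowOrder = rh$order, colOrder = ch$order,
         rowHclust = rh, colHclust = ch)
}
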