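## Clinical-annotation enrichment, probe-variability comparison,
## tumor-normal deltas and branch enrichment utilities.

#' Packaged cohort characteristics table
#'
#' Per-subgroup counts of clinical and molecular annotation levels for the
#' 98-tumor reference cohort (stage, grade, TP53/FGFR3 mutation status,
#' expression subtype, epitype). The `"NA"` epitype level marks samples
#' without an epitype assignment; the `"Tx"` stage level marks the single
#' sample of unknown stage.
#'
#' @return data.frame with columns annotation, level, total, sg1..sg4.
#' @export
table1Counts <- function() {
    path <- system.file("extdata", "table1.tsv", package = "dmrscape",
                        mustWork = TRUE)
    utils::read.delim(path, colClasses = c("character", "character",
                                           rep("integer", 5)),
                      na.strings = character())
}

#' One-vs-rest Fisher enrichment from per-subgroup level counts
#'
#' Builds the 2x2 table [in-subgroup & level, in-subgroup & other;
#' rest & level, rest & other] from a counts table in the
#' [table1Counts()] layout and runs a two-sided Fisher test
#' (point-probability rule). Samples with a missing annotation (level
#' `"NA"`) are excluded from that annotation's tests.
#'
#' @param annotation annotation name (e.g. `"grade"`).
#' @param level tested level (e.g. `"3"`).
#' @param subgroup subgroup index 1-4.
#' @param counts counts table; defaults to the packaged cohort table.
#' @return list with `counts` (2x2), `odds_ratio`, `p`, `direction`.
#' @export
enrichmentFromCounts <- function(annotation, level, subgroup,
                                 counts = table1Counts()) {
    rows <- counts[counts$annotation == annotation &
                       counts$level != "NA", ]
    if (!level %in% rows$level)
        stop("unknown level '", level, "' for annotation '", annotation,
             "'")
    sgCol <- paste0("sg", subgroup)
    a <- rows[rows$level == level, sgCol]
    inTotal <- sum(rows[[sgCol]])
    levelTotal <- sum(rows$total[rows$level == level])
    allTotal <- sum(rows$total)
    ft <- fisher2x2(a, inTotal - a, levelTotal - a,
                    allTotal - levelTotal - (inTotal - a))
    ft$direction <- if (ft$odds_ratio > 1) "enriched" else
        if (ft$odds_ratio < 1) "depleted" else "none"
    ft
}

#' One-vs-rest Fisher enrichment from a sample table
#'
#' Dichotomizes an annotation as level vs not-level (dropping samples with
#' `NA` in that annotation), then tests one subgroup against the rest with
#' a two-sided Fisher test.
#'
#' @param sampleTable data.frame with per-sample annotations.
#' @param subgroups subgroup label per sample (same order).
#' @param annotation column name tested.
#' @param level tested level of that column.
#' @param subgroup the subgroup tested against the rest.
#' @return list with `counts` (2x2), `odds_ratio`, `p`, `direction`.
#' @export
oneVsRestFisher <- function(sampleTable, subgroups, annotation, level,
                            subgroup) {
    vals <- sampleTable[[annotation]]
    if (is.null(vals)) stop("unknown annotation: ", annotation)
    keep <- !is.na(vals) & vals != "NA"
    vals <- vals[keep]; sg <- subgroups[keep]
    if (!any(sg == subgroup))
        stop("subgroup ", subgroup, " is empty after NA exclusion")
    isLevel <- vals == level
    inGroup <- sg == subgroup
    ft <- fisher2x2(sum(inGroup & isLevel), sum(inGroup & !isLevel),
                    sum(!inGroup & isLevel), sum(!inGroup & !isLevel))
    ft$direction <- if (ft$odds_ratio > 1) "enriched" else
        if (ft$odds_ratio < 1) "depleted" else "none"
    ft
}

#' Compare probe variability inside vs outside DMRs
#'
#' Splits per-probe across-sample standard deviations by DMR overlap and
#' tests the two groups with a two-sided Mann-Whitney test.
#'
#' @param pm a [ProbeMatrix-class].
#' @param dmrs [DMRSet-class] or [GenomicRanges::GRanges].
#' @return list with `sdIn`, `sdOut`, `statistic`, `p`.
#' @export
compareProbeSd <- function(pm, dmrs) {
    gr <- if (is(dmrs, "DMRSet")) rowRanges(dmrs) else dmrs
    inside <- overlapsAny(rowRanges(pm), gr)
    sds <- rowSdsFast(probeScores(pm))
    if (sum(inside) < 2 || sum(!inside) < 2)
        stop("both probe groups need at least 2 probes")
    ht <- suppressWarnings(stats::wilcox.test(sds[inside], sds[!inside]))
    list(sdIn = sds[inside], sdOut = sds[!inside],
         statistic = unname(ht$statistic), p = ht$p.value)
}

#' Tumor-minus-normal methylation differences per pattern
#'
#' @param mat feature matrix (probes or DMRs x samples).
#' @param tumorIds,normalIds column ids of the two groups.
#' @param patterns pattern label per feature.
#' @return data.frame (pattern, meanDelta, sign) plus per-feature deltas in
#'   `attr(, "delta")`.
#' @export
tumorNormalDelta <- function(mat, tumorIds, normalIds, patterns) {
    delta <- rowMeans(mat[, tumorIds, drop = FALSE]) -
        rowMeans(mat[, normalIds, drop = FALSE])
    levs <- sort(unique(patterns[!is.na(patterns)]))
    out <- data.frame(
        pattern = levs,
        meanDelta = vapply(levs, function(p)
            mean(delta[which(patterns == p)]), numeric(1)))
    out$sign <- sign(out$meanDelta)
    attr(out, "delta") <- delta
    out
}

#' Branch-wise enrichment of pattern membership
#'
#' For each branch of a feature dendrogram cut, tests each pattern's
#' membership one-vs-rest with a two-sided Fisher test.
#'
#' @param branches branch label per feature.
#' @param patterns pattern label per feature (NA = no pattern).
#' @return data.frame (branch, pattern, counts, odds_ratio, p).
#' @export
branchEnrichment <- function(branches, patterns) {
    out <- list()
    for (b in sort(unique(branches))) {
        inB <- branches == b
        for (p in sort(unique(patterns[!is.na(patterns)]))) {
            isP <- !is.na(patterns) & patterns == p
            ft <- fisher2x2(sum(inB & isP), sum(inB & !isP),
                            sum(!inB & isP), sum(!inB & !isP))
            out[[length(out) + 1]] <- data.frame(
                branch = b, pattern = p, in_branch = sum(inB & isP),
                odds_ratio = ft$odds_ratio, p = ft$p)
        }
    }
    do.call(rbind, out)
}
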