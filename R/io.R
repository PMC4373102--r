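## Readers, writers and validators for the on-disk formats: probe-matrix
## TSV, BED3/BED4 tracks (0-based half-open on disk, converted to the
## 1-based closed GRanges convention in memory), expression TSV, sample
## annotation TSV and ground-truth JSON.

.autosomes <- paste0("chr", 1:22)

#' Read a probe-level methylation matrix
#'
#' Expects a tab-separated file with header
#' `probe_id chrom start end cpg_count <sample...>`; coordinates on disk
#' are 0-based half-open.
#'
#' @param path file path.
#' @param autosomesOnly drop probes outside chr1..chr22.
#' @return A [ProbeMatrix-class].
#' @export
readProbeMatrix <- function(path, autosomesOnly = FALSE) {
    df <- utils::read.delim(path, check.names = FALSE)
    need <- c("probe_id", "chrom", "start", "end", "cpg_count")
    if (!all(need %in% colnames(df)))
        stop("probe matrix must have columns: ",
             paste(need, collapse = ", "))
    bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                     df$end <= df$start)
    if (length(bad) > 0)
        stop("malformed probe coordinates at line ", bad[1] + 1)
    if (autosomesOnly)
        df <- df[df$chrom %in% .autosomes, , drop = FALSE]
    gr <- GRanges(df$chrom, IRanges(df$start + 1, df$end),
                  cpg_count = as.integer(df$cpg_count))
    names(gr) <- df$probe_id
    ProbeMatrix(gr, as.matrix(df[, setdiff(colnames(df), need),
                                 drop = FALSE]))
}

#' @rdname readProbeMatrix
#' @param pm a [ProbeMatrix-class].
#' @export
writeProbeMatrix <- function(pm, path) {
    rr <- rowRanges(pm)
    df <- data.frame(probe_id = names(rr),
                     chrom = as.character(seqnames(rr)),
                     start = start(rr) - 1, end = end(rr),
                     cpg_count = mcols(rr)$cpg_count,
                     check.names = FALSE)
    df <- cbind(df, as.data.frame(probeScores(pm), check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a BED3/BED4 track
#'
#' The optional fourth column becomes a `state` column (for
#' `kind = "segmentation"`, validated as integers 1-15 tiling without
#' overlap) or a `label` column otherwise. Coordinates on disk are 0-based
#' half-open.
#'
#' @param path file path.
#' @param kind `"intervals"`, `"segmentation"` or `"peaks"`.
#' @return A [GenomicRanges::GRanges].
#' @export
readBed <- function(path, kind = c("intervals", "segmentation", "peaks")) {
    kind <- match.arg(kind)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3))
        stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
    chrom <- vapply(fields, `[`, character(1), 1)
    start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1),
                                                2)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1),
                                              3)))
    bad <- which(is.na(start) | is.na(end) | end <= start | start < 0)
    if (length(bad) > 0)
        stop("malformed BED line ", bad[1], ": bad coordinates")
    gr <- GRanges(chrom, IRanges(start + 1, end))
    if (any(nf >= 4)) {
        name <- vapply(fields, function(f)
            if (length(f) >= 4) f[4] else NA_character_, character(1))
        if (kind == "segmentation") {
            st <- suppressWarnings(as.integer(name))
            bad <- which(is.na(st) | st < 1L | st > 15L)
            if (length(bad) > 0)
                stop("malformed BED line ", bad[1],
                     ": segmentation state must be 1..15")
            mcols(gr)$state <- st
        } else {
            mcols(gr)$label <- name
        }
    } else if (kind == "segmentation") {
        stop("segmentation BED requires a state column")
    }
    if (kind == "segmentation" &&
        length(findOverlaps(gr, drop.self = TRUE,
                            drop.redundant = TRUE)) > 0)
        stop("segmentation track has overlapping segments")
    sort(gr)
}

#' @rdname readBed
#' @param gr a [GenomicRanges::GRanges] to write (0-based half-open on
#'   disk); a `state` or `label` column becomes the BED name field.
#' @export
writeBed <- function(gr, path) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = format(start(gr) - 1, scientific = FALSE,
                                    trim = TRUE),
                     end = format(end(gr), scientific = FALSE, trim = TRUE))
    mc <- mcols(gr)
    if ("state" %in% colnames(mc)) df$name <- mc$state
    else if ("label" %in% colnames(mc)) df$name <- mc$label
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read or write an expression matrix (genes x samples TSV)
#'
#' @param path file path.
#' @return numeric matrix with gene row names.
#' @export
readExpression <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    if (colnames(df)[1] != "gene_id")
        stop("expression table must start with a gene_id column")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene_id
    if (anyNA(m)) stop("expression matrix contains missing values")
    m
}

#' @rdname readExpression
#' @param m expression matrix.
#' @export
writeExpression <- function(m, path) {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.sampleCategories <- list(
    stage = c("Ta", "T1", "MI", "Tx"),
    grade = c("1", "2", "3"),
    tp53 = c("mut", "wt"),
    fgfr3 = c("mut", "wt"),
    epitype = c("A", "B", "C", "D"))

#' Validate a sample annotation table
#'
#' Checks closed categories (stage Ta/T1/MI/Tx, grade 1-3, tp53 and fgfr3
#' mut/wt, epitype A-D; `NA` allowed everywhere), non-negative survival
#' times and 0/1 event indicators.
#'
#' @param df sample table.
#' @return the table, invisibly; errors on violation.
#' @export
validateSampleTable <- function(df) {
    if (!"sample_id" %in% colnames(df)) stop("sample_id column required")
    for (col in names(.sampleCategories)) {
        if (!col %in% colnames(df)) next
        vals <- as.character(df[[col]])
        ok <- is.na(vals) | vals == "NA" |
            vals %in% .sampleCategories[[col]]
        if (!all(ok))
            stop("unknown ", col, " category: ",
                 paste(unique(vals[!ok]), collapse = ", "))
    }
    if ("survival_time" %in% colnames(df) &&
        any(df$survival_time < 0, na.rm = TRUE))
        stop("survival_time must be >= 0")
    if ("event" %in% colnames(df) &&
        !all(df$event %in% c(0L, 1L, NA)))
        stop("event must be 0 or 1")
    invisible(df)
}

#' Read or write a sample annotation table
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
readSampleTable <- function(path) {
    df <- utils::read.delim(path, colClasses = "character",
                            check.names = FALSE)
    for (col in c("survival_time"))
        if (col %in% colnames(df)) df[[col]] <- as.numeric(df[[col]])
    for (col in c("event", "subgroup"))
        if (col %in% colnames(df)) df[[col]] <- as.integer(df[[col]])
    validateSampleTable(df)
    df
}

#' @rdname readSampleTable
#' @param df sample table.
#' @export
writeSampleTable <- function(df, path) {
    validateSampleTable(df)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write or read simulation ground truth as JSON
#'
#' @param truth a [SyntheticTruth-class].
#' @param path file path.
#' @export
writeTruth <- function(truth, path) {
    dmr <- truth@dmrRanges
    obj <- list(
        dmrs = data.frame(dmr_id = mcols(dmr)$dmr_id,
                          chrom = as.character(seqnames(dmr)),
                          start = start(dmr) - 1, end = end(dmr),
                          pattern = mcols(dmr)$pattern),
        subgroups = as.list(truth@subgroups),
        expr_pairs = truth@exprPairs)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    obj <- jsonlite::fromJSON(path)
    gr <- GRanges(obj$dmrs$chrom,
                  IRanges(obj$dmrs$start + 1, obj$dmrs$end),
                  dmr_id = obj$dmrs$dmr_id,
                  pattern = as.integer(obj$dmrs$pattern))
    names(gr) <- obj$dmrs$dmr_id
    pairs <- as.data.frame(obj$expr_pairs)
    if (nrow(pairs) == 0)
        pairs <- data.frame(dmr_id = character(), gene_id = character(),
                            sign = integer())
    new("SyntheticTruth", dmrRanges = gr,
        subgroups = unlist(obj$subgroups),
        exprPairs = pairs)
}
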