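## Five-step normalization of two-channel MeDIP-chip intensities to
## probe-level methylation scores. Each step can be switched off so
## alternate schemes can be substituted.

#' Normalization parameters
#'
#' @param smoothingWindow odd number of adjacent probes averaged in the
#'   final smoothing step.
#' @param cpgBiasSpan loess span for the CpG-count bias fit, in (0, 1].
#' @param maxGapBp smoothing never crosses inter-probe gaps larger than
#'   this.
#' @param steps named logical flags enabling the five steps: `logratio`,
#'   `median_center`, `quantile`, `cpg_bias`, `smooth`.
#' @return a validated parameter list.
#' @export
normParams <- function(smoothingWindow = 3L, cpgBiasSpan = 0.75,
                       maxGapBp = 500L,
                       steps = c(logratio = TRUE, median_center = TRUE,
                                 quantile = TRUE, cpg_bias = TRUE,
                                 smooth = TRUE)) {
    .assertOddWindow(as.integer(smoothingWindow))
    if (cpgBiasSpan <= 0 || cpgBiasSpan > 1)
        stop("cpgBiasSpan must lie in (0, 1]")
    need <- c("logratio", "median_center", "quantile", "cpg_bias", "smooth")
    if (!all(need %in% names(steps)))
        stop("steps must name all of: ", paste(need, collapse = ", "))
    list(smoothingWindow = as.integer(smoothingWindow),
         cpgBiasSpan = cpgBiasSpan, maxGapBp = as.integer(maxGapBp),
         steps = steps)
}

#' Normalize two-channel probe intensities to methylation scores
#'
#' Applies, in order: (1) per-probe log2(IP/input); (2) per-array median
#' centering; (3) across-array quantile normalization
#' ([limma::normalizeQuantiles()]); (4) per-array CpG-count bias removal by
#' subtracting a loess fit of score on probe CpG count; (5) a running mean
#' over `smoothingWindow` adjacent probes, never crossing inter-probe gaps
#' above `maxGapBp`. After step 2 every array has median zero (to 1e-9)
#' until steps 4-5 perturb it.
#'
#' @param ip,input strictly positive intensity matrices, probes x arrays.
#' @param ranges [GenomicRanges::GRanges] of probe footprints (named by
#'   probe id) with `cpg_count` metadata.
#' @param params a [normParams()] list.
#' @param colData optional sample annotation for the result.
#' @return A [ProbeMatrix-class] of normalized scores.
#' @examples
#' cfg <- simConfig(nDmrsPerPattern = c(4, 4, 8), nNullProbes = 200,
#'                  nPerSubgroup = c(3, 3, 3, 3), nNormals = 0)
#' sim <- simulateProbeMatrix(cfg)
#' raw <- simulateRawIntensities(sim$probes)
#' norm <- normalizeProbes(raw$ip, raw$input, rowRanges(sim$probes))
#' @export
normalizeProbes <- function(ip, input, ranges, params = normParams(),
                            colData = NULL) {
    ip <- as.matrix(ip); input <- as.matrix(input)
    stopifnot(identical(dim(ip), dim(input)),
              nrow(ip) == length(ranges))
    st <- params$steps
    if (st[["logratio"]]) {
        bad <- which(ip <= 0 | input <= 0, arr.ind = TRUE)
        if (nrow(bad) > 0) {
            id <- if (!is.null(names(ranges))) names(ranges)[bad[1, 1]]
                  else bad[1, 1]
            stop("nonpositive intensity at probe ", id,
                 " (array ", bad[1, 2], ")")
        }
    }
    score <- if (st[["logratio"]]) log2(ip / input) else ip

    if (st[["median_center"]])
        score <- sweep(score, 2, apply(score, 2, stats::median))

    if (st[["quantile"]])
        score <- limma::normalizeQuantiles(score)

    if (st[["cpg_bias"]]) {
        cpg <- mcols(ranges)$cpg_count
        if (length(unique(cpg)) > 2) {
            for (j in seq_len(ncol(score))) {
                if (stats::sd(score[, j]) == 0) next
                # cpg counts are small integers; loess on the discrete
                # predictor is well-defined but noisy-design warnings fire
                fit <- suppressWarnings(
                    stats::loess(score[, j] ~ cpg,
                                 span = params$cpgBiasSpan, degree = 1))
                score[, j] <- score[, j] -
                    suppressWarnings(stats::predict(fit, cpg))
            }
        }
    }

    if (st[["smooth"]]) {
        ord <- order(as.integer(seqnames(ranges)), start(ranges))
        chromTab <- table(as.character(seqnames(ranges)))
        if (any(chromTab < params$smoothingWindow))
            warning("smoothing window truncated on chromosome(s) with ",
                    "fewer probes than the window")
        score[ord, ] <- gapAwareRunningMean(
            score[ord, , drop = FALSE],
            as.character(seqnames(ranges))[ord],
            start(ranges)[ord], end(ranges)[ord],
            params$smoothingWindow, params$maxGapBp)
    }

    dimnames(score) <- dimnames(ip)
    ProbeMatrix(ranges, score, colData = colData)
}
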