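#' Flag high-confidence probe pairs from paired same-sample experiments
#'
#' Some probe pairs disagree systematically between platforms even though
#' they share a cg-number prefix (probe redesign, chemistry change). When
#' the same biological samples have been profiled on both platforms, those
#' platform-specific biases are observable directly: a pair is flagged
#' high-confidence when its absolute cross-platform beta difference stays
#' within \code{delta} (inclusive) in at least \code{minPairs} of the paired
#' experiments. Only experiments where both readings are present count
#' toward \code{minPairs}; pairs with fewer than \code{minPairs} evaluable
#' experiments are flagged \code{FALSE} and their count is reported in a
#' message. The pair set itself is unchanged — use
#' \code{\link{applyBiasFilter}} to drop the low-confidence pairs.
#'
#' The shipped defaults (\code{delta = 0.05}, \code{minPairs = 4}) reflect
#' a five-experiment cell-line benchmark requiring agreement within 0.05 in
#' four of the pairs.
#'
#' @param mapping a \linkS4class{MappingTable}.
#' @param experiments nonempty list of \linkS4class{PairedExperiment}.
#' @param delta beta-difference threshold in (0, 1); the comparison is
#'   inclusive (differences equal to \code{delta} pass).
#' @param minPairs minimum number of agreeing experiments, between 1 and
#'   \code{length(experiments)}.
#' @return the \linkS4class{MappingTable} with \code{High_Confidence}
#'   recomputed.
#' @export
buildHighConfidenceMapping <- function(mapping, experiments, delta = 0.05,
                                       minPairs = 4L) {
    stopifnot(is(mapping, "MappingTable"))
    if (length(experiments) == 0L)
        stop("'experiments' must be nonempty")
    if (!all(vapply(experiments, is, logical(1L), "PairedExperiment")))
        stop("'experiments' must be PairedExperiment objects")
    if (delta <= 0 || delta >= 1)
        stop("'delta' must lie in (0, 1)")
    minPairs <- as.integer(minPairs)
    if (minPairs < 1L || minPairs > length(experiments))
        stop("'minPairs' must be between 1 and the number of experiments")
    pairs <- mappingPairs(mapping)
    nAgree <- nEval <- integer(nrow(pairs))
    for (exp in experiments) {
        src <- exp@sourceBetas[pairs$Source_ID]
        tgt <- exp@targetBetas[pairs$Target_ID]
        both <- !is.na(src) & !is.na(tgt)
        nEval <- nEval + both
        nAgree <- nAgree + (both & abs(src - tgt) <= delta)
    }
    short <- nEval < minPairs
    if (any(short))
        message(sum(short), " pair(s) had fewer than ", minPairs,
                " evaluable experiments and were flagged low-confidence")
    pairs$High_Confidence <- nAgree >= minPairs
    new("MappingTable", sourcePlatform = sourcePlatform(mapping),
        targetPlatform = targetPlatform(mapping), pairs = pairs)
}

#' Restrict a mapping to its high-confidence pairs
#'
#' @param mapping a \linkS4class{MappingTable} with
#'   \code{High_Confidence} flags set.
#' @return a \linkS4class{MappingTable} containing only the flagged pairs.
#' @export
applyBiasFilter <- function(mapping) {
    stopifnot(is(mapping, "MappingTable"))
    pairs <- mappingPairs(mapping)
    keep <- pairs[pairs$High_Confidence, , drop = FALSE]
    rownames(keep) <- NULL
    if (nrow(keep) == 0L)
        warning("no high-confidence pairs remain after bias filtering")
    new("MappingTable", sourcePlatform = sourcePlatform(mapping),
        targetPlatform = targetPlatform(mapping), pairs = keep)
}
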