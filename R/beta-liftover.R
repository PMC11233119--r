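#' Aggregate replicate probe readings into one beta value
#'
#' When several probe designs (replicates) measure the same CpG, their
#' readings are resolved per sample by one of two strategies: \code{"mean"}
#' averages the non-missing betas; \code{"best_detection"} keeps the reading
#' with the smallest detection p-value among unmasked candidates, on the
#' grounds that the most significantly detected design is the most reliable.
#'
#' Missing values are skipped, never treated as zeros; if every value is
#' missing the result is \code{NA}. Under \code{best_detection}, candidates
#' are the readings that are non-missing, unmasked and have a detection
#' p-value; ties at the smallest p are broken by the lexicographically
#' lowest probe ID, and if no candidate remains (all masked or all p
#' missing) the mean of the non-missing values is used as fallback. Under
#' \code{mean}, masked readings are included unless
#' \code{respectMask = TRUE}.
#'
#' @param values numeric vector of beta readings (may contain \code{NA}).
#' @param strategy \code{"mean"} or \code{"best_detection"}.
#' @param detectionP detection p-values aligned to \code{values}; required
#'   for \code{best_detection}.
#' @param masked logical mask flags aligned to \code{values}; default all
#'   unmasked.
#' @param ids probe IDs aligned to \code{values}, used only for the
#'   deterministic tie-break; default positional order.
#' @param respectMask drop masked readings under \code{mean}.
#' @return a single beta value in [0,1], or \code{NA}.
#' @examples
#' aggregateReplicates(c(0.2, 0.4), "mean")
#' aggregateReplicates(c(0.2, 0.9), "best_detection",
#'                     detectionP = c(0.5, 0.001))
#' @export
aggregateReplicates <- function(values,
                                strategy = c("mean", "best_detection"),
                                detectionP = NULL, masked = NULL,
                                ids = NULL, respectMask = FALSE) {
    strategy <- match.arg(strategy)
    if (length(values) == 0L)
        stop("'values' must be nonempty")
    if (is.null(masked)) masked <- rep(FALSE, length(values))
    if (is.null(ids)) ids <- sprintf("%09d", seq_along(values))
    if (strategy == "mean") {
        keep <- !is.na(values) & !(respectMask & masked)
        if (!any(keep)) return(NA_real_)
        return(mean(values[keep]))
    }
    if (is.null(detectionP))
        stop("strategy 'best_detection' requires 'detectionP'")
    if (length(detectionP) != length(values))
        stop("'detectionP' must be aligned to 'values'")
    cand <- !is.na(values) & !masked & !is.na(detectionP)
    if (!any(cand)) {       # all masked or p unavailable: fall back to mean
        if (all(is.na(values))) return(NA_real_)
        return(mean(values, na.rm = TRUE))
    }
    idx <- which(cand)
    best <- idx[detectionP[idx] == min(detectionP[idx])]
    if (length(best) > 1L) best <- best[order(ids[best])][1L]
    values[best]
}

.detectionMatrices <- function(b, signal) {
    ids <- probeIDs(b)
    ns <- ncol(betaValues(b))
    p <- matrix(NA_real_, length(ids), ns, dimnames = list(ids, sampleIDs(b)))
    msk <- matrix(FALSE, length(ids), ns, dimnames = dimnames(p))
    if (is.null(signal)) return(list(p = p, mask = msk))
    frames <- if (is(signal, "SignalFrame")) rep(list(signal), ns)
              else signal
    if (length(frames) != ns)
        stop("'signal' must be one SignalFrame or a list of one per sample")
    for (j in seq_len(ns)) {
        r <- signalRecords(frames[[j]])
        hit <- match(ids, r$Probe_ID)
        p[, j] <- r$Detection_P[hit]
        msk[, j] <- ifelse(is.na(hit), FALSE, r$Mask[hit])
    }
    list(p = p, mask = msk)
}

#' Convert a beta-value matrix to another platform
#'
#' Translates the rows of a \linkS4class{BetaMatrix} through a
#' \linkS4class{MappingTable}: a target probe fed by several source
#' replicates gets the per-sample \code{\link{aggregateReplicates}} of those
#' readings; a source probe fanning out to several target replicates has its
#' reading broadcast verbatim to each of them. Target probes with no source
#' feed are absent from the output — they are the candidates for
#' \code{\link{imputeMissing}}. Samples (columns) are preserved in order;
#' output rows are the distinct target IDs in lexicographic order.
#'
#' Mapping pairs whose source probe is absent from \code{b} are skipped with
#' a message reporting the count.
#'
#' @param b a \linkS4class{BetaMatrix} on the mapping's source platform.
#' @param mapping a \linkS4class{MappingTable}.
#' @param strategy replicate aggregation strategy, see
#'   \code{\link{aggregateReplicates}}.
#' @param signal optional detection p-value source for
#'   \code{best_detection} and for masks: a single \linkS4class{SignalFrame}
#'   (applied to every sample) or a list with one frame per sample.
#' @param respectMask exclude masked readings from \code{mean} aggregation;
#'   requires \code{signal}.
#' @return a \linkS4class{BetaMatrix} on the target platform with
#'   \code{origin = "converted"}.
#' @examples
#' src <- ProbeManifest("EPIC", c("cg01", "cg02"))
#' tgt <- ProbeManifest("EPICv2", c("cg01_TC11", "cg01_BC11", "cg02_TC21"))
#' map <- buildIdMapping(src, tgt)
#' b <- BetaMatrix("EPIC", matrix(c(0.1, 0.9), 2, 1,
#'                 dimnames = list(c("cg01", "cg02"), "s1")))
#' betaValues(convertBeta(b, map))
#' @export
convertBeta <- function(b, mapping, strategy = c("mean", "best_detection"),
                        signal = NULL, respectMask = FALSE) {
    strategy <- match.arg(strategy)
    stopifnot(is(b, "BetaMatrix"), is(mapping, "MappingTable"))
    if (platform(b) != sourcePlatform(mapping))
        stop("beta matrix platform '", platform(b),
             "' does not match mapping source platform '",
             sourcePlatform(mapping), "'")
    if (strategy == "best_detection" && is.null(signal))
        stop("strategy 'best_detection' requires 'signal'")
    if (respectMask && is.null(signal))
        stop("'respectMask' requires 'signal' (masks live in SignalFrames)")
    pairs <- mappingPairs(mapping)
    present <- pairs$Source_ID %in% probeIDs(b)
    if (any(!present))
        message(sum(!present),
                " mapping pair(s) reference source probes absent from the",
                " beta matrix; skipped")
    pairs <- pairs[present, , drop = FALSE]
    vals <- betaValues(b)
    dm <- .detectionMatrices(b, signal)
    targets <- sort(unique(pairs$Target_ID))
    out <- matrix(NA_real_, length(targets), ncol(vals),
                  dimnames = list(targets, colnames(vals)))
    grp <- split(pairs$Source_ID, pairs$Target_ID)
    sizes <- lengths(grp)
    # single-feed targets (incl. replicate broadcast) are verbatim copies,
    # except when masked readings must be dropped
    single <- if (respectMask && strategy == "mean") character()
              else names(grp)[sizes == 1L]
    if (length(single))
        out[single, ] <- vals[unlist(grp[single], use.names = FALSE), ,
                              drop = FALSE]
    for (tgt in setdiff(names(grp), single)) {
        src <- sort(grp[[tgt]])
        for (j in seq_len(ncol(vals))) {
            out[tgt, j] <- aggregateReplicates(
                vals[src, j], strategy,
                detectionP = dm$p[src, j], masked = dm$mask[src, j],
                ids = src, respectMask = respectMask)
        }
    }
    BetaMatrix(targetPlatform(mapping), out, origin = "converted")
}

#' Read / write beta-value matrices as TSV
#'
#' First column \code{Probe_ID}, one column per sample, missing values
#' rendered as \code{NA}.
#'
#' @param path file path.
#' @param platform platform label for the matrix being read.
#' @param origin provenance label for the matrix being read.
#' @param b a \linkS4class{BetaMatrix} to write.
#' @return \code{readBetaMatrix} returns a \linkS4class{BetaMatrix}; the
#'   writer returns the path invisibly.
#' @name beta-io
NULL

#' @rdname beta-io
#' @export
readBetaMatrix <- function(path, platform, origin = "measured") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(d[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- d$Probe_ID
    BetaMatrix(platform, m, origin = origin)
}

#' @rdname beta-io
#' @export
writeBetaMatrix <- function(b, path) {
    stopifnot(is(b, "BetaMatrix"))
    d <- data.frame(Probe_ID = probeIDs(b), betaValues(b),
                    check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
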