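#' Convert a signal-intensity frame to another platform
#'
#' Lifts raw (M, U) intensity records through a probe mapping so that
#' intensity-based analyses (copy-number profiling in particular) can run
#' on the target platform's probe set. Records are transferred verbatim —
#' intensities are never averaged, since averaging raw signal across
#' differently designed probes conflates chemistry. When several source
#' replicates feed one target probe, the record with the smallest detection
#' p-value among unmasked candidates is chosen (ties broken by lowest
#' source probe ID; if every candidate is masked the least-p masked record
#' is used and keeps \code{Mask = TRUE} so downstream can exclude it). A
#' source record fanning out to several target replicates is duplicated per
#' target. Target probes with no source feed are absent: signal imputation
#' is not supported.
#'
#' When both manifests are supplied, pairs whose source and target
#' chemistry differ are counted and reported (records still transfer
#' verbatim).
#'
#' @param s a \linkS4class{SignalFrame} on the mapping's source platform.
#' @param mapping a \linkS4class{MappingTable}.
#' @param sourceManifest,targetManifest optional
#'   \linkS4class{ProbeManifest}s enabling the chemistry-mismatch report.
#' @return a \linkS4class{SignalFrame} on the target platform, rows ordered
#'   by target probe ID.
#' @export
convertSignal <- function(s, mapping, sourceManifest = NULL,
                          targetManifest = NULL) {
    stopifnot(is(s, "SignalFrame"), is(mapping, "MappingTable"))
    if (platform(s) != sourcePlatform(mapping))
        stop("signal platform '", platform(s),
             "' does not match mapping source platform '",
             sourcePlatform(mapping), "'")
    pairs <- mappingPairs(mapping)
    rec <- signalRecords(s)
    present <- pairs$Source_ID %in% rec$Probe_ID
    if (any(!present))
        message(sum(!present),
                " mapping pair(s) reference source probes absent from the",
                " signal frame; skipped")
    pairs <- pairs[present, , drop = FALSE]
    if (!is.null(sourceManifest) && !is.null(targetManifest)) {
        sc <- manifestProbes(sourceManifest)
        tc <- manifestProbes(targetManifest)
        chemS <- sc$Chemistry[match(pairs$Source_ID, sc$Probe_ID)]
        chemT <- tc$Chemistry[match(pairs$Target_ID, tc$Probe_ID)]
        nMismatch <- sum(!is.na(chemS) & !is.na(chemT) & chemS != chemT)
        if (nMismatch)
            message(nMismatch, " pair(s) map across Infinium chemistries;",
                    " records transferred verbatim")
    }
    grp <- split(pairs$Source_ID, pairs$Target_ID)
    pick <- vapply(grp, function(src) {
        if (length(src) == 1L) return(src)
        src <- sort(src)
        i <- match(src, rec$Probe_ID)
        p <- rec$Detection_P[i]
        msk <- rec$Mask[i]
        cand <- if (any(!msk)) which(!msk) else seq_along(src)
        pc <- p[cand]
        pc[is.na(pc)] <- Inf             # missing p ranks worst
        src[cand[which.min(pc)]]         # which.min: lowest ID on ties
    }, character(1L))
    i <- match(pick, rec$Probe_ID)
    out <- data.frame(Probe_ID = names(grp), M = rec$M[i], U = rec$U[i],
                      Detection_P = rec$Detection_P[i], Mask = rec$Mask[i],
                      stringsAsFactors = FALSE)
    out <- out[order(out$Probe_ID), , drop = FALSE]
    rownames(out) <- NULL
    new("SignalFrame", platform = targetPlatform(mapping), records = out)
}

#' Total per-probe signal intensity
#'
#' Returns M + U per probe, the quantity copy-number workflows start from.
#' Masked probes are included but flagged via the \code{"masked"}
#' attribute.
#'
#' @param s a \linkS4class{SignalFrame}.
#' @return named numeric vector of total intensities with a named logical
#'   \code{"masked"} attribute.
#' @export
totalIntensity <- function(s) {
    stopifnot(is(s, "SignalFrame"))
    rec <- signalRecords(s)
    out <- stats::setNames(rec$M + rec$U, rec$Probe_ID)
    attr(out, "masked") <- stats::setNames(rec$Mask, rec$Probe_ID)
    out
}

#' Read / write signal frames as TSV
#'
#' Columns \code{Probe_ID, M, U, Detection_P, Mask}; missing detection
#' p-values rendered as \code{NA}.
#'
#' @param path file path.
#' @param platform platform label for the frame being read.
#' @param s a \linkS4class{SignalFrame} to write.
#' @return \code{readSignalFrame} returns a \linkS4class{SignalFrame}; the
#'   writer returns the path invisibly.
#' @name signal-io
NULL

#' @rdname signal-io
#' @export
readSignalFrame <- function(path, platform) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(Probe_ID = "character",
                                          M = "numeric", U = "numeric",
                                          Detection_P = "numeric",
                                          Mask = "logical"))
    new("SignalFrame", platform = platform, records = d)
}

#' @rdname signal-io
#' @export
writeSignalFrame <- function(s, path) {
    stopifnot(is(s, "SignalFrame"))
    utils::write.table(signalRecords(s), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
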