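#' @import methods
NULL

#' ProbeManifest: a per-platform probe catalog
#'
#' Holds one platform's probe records: full probe ID, Infinium chemistry
#' ("I"/"II") and a design-mask flag marking probes with known quality
#' issues. Probe IDs must be unique and, when a design suffix is present, the
#' chemistry column must agree with the suffix's chemistry digit.
#'
#' @slot platform platform label, e.g. "EPICv2".
#' @slot probes data.frame with columns \code{Probe_ID}, \code{Prefix},
#'   \code{Chemistry}, \code{Mask}.
#' @seealso \code{\link{ProbeManifest}} constructor,
#'   \code{\link{replicateGroups}}, \code{\link{buildIdMapping}}
#' @exportClass ProbeManifest
setClass("ProbeManifest",
    representation(platform = "character", probes = "data.frame"))

setValidity("ProbeManifest", function(object) {
    p <- object@probes
    msg <- character()
    need <- c("Probe_ID", "Prefix", "Chemistry", "Mask")
    if (!all(need %in% names(p)))
        return(paste("probes must have columns",
                     paste(need, collapse = ", ")))
    if (length(object@platform) != 1L || is.na(object@platform))
        msg <- c(msg, "platform must be a single string")
    if (anyDuplicated(p$Probe_ID))
        msg <- c(msg, "probe IDs must be unique within a manifest")
    if (!all(p$Chemistry %in% c("I", "II")))
        msg <- c(msg, "Chemistry must be 'I' or 'II'")
    if (!is.logical(p$Mask))
        msg <- c(msg, "Mask must be logical")
    if (nrow(p) > 0L) {
        parsed <- parseProbeID(p$Probe_ID)
        suf <- !is.na(parsed$Chemistry)
        if (any(suf) && !all(parsed$Chemistry[suf] == p$Chemistry[suf]))
            msg <- c(msg, "Chemistry column conflicts with suffix chemistry")
        if (!all(parsed$Prefix == p$Prefix))
            msg <- c(msg, "Prefix column must equal the parsed prefix")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ProbeManifest
#'
#' @param platform platform label.
#' @param probeIDs character vector of probe IDs (legacy or suffixed style).
#' @param chemistry "I"/"II" per probe; defaults to the suffix chemistry when
#'   present and "II" otherwise.
#' @param mask logical design-mask flags; default all \code{FALSE}.
#' @return a \linkS4class{ProbeManifest}.
#' @examples
#' ProbeManifest("EPICv2", c("cg00000029_TC21", "cg00000029_BC21", "cg03"))
#' @export
ProbeManifest <- function(platform, probeIDs, chemistry = NULL, mask = NULL) {
    parsed <- parseProbeID(probeIDs)
    if (is.null(chemistry)) {
        chemistry <- parsed$Chemistry
        chemistry[is.na(chemistry)] <- "II"
    }
    if (is.null(mask)) mask <- rep(FALSE, length(probeIDs))
    new("ProbeManifest", platform = platform,
        probes = data.frame(Probe_ID = parsed$ProbeID,
                            Prefix = parsed$Prefix,
                            Chemistry = chemistry, Mask = mask,
                            stringsAsFactors = FALSE))
}

setMethod("show", "ProbeManifest", function(object) {
    p <- object@probes
    nrep <- sum(duplicated(p$Prefix) | duplicated(p$Prefix, fromLast = TRUE))
    cat("ProbeManifest [", object@platform, "]: ", nrow(p), " probes, ",
        length(unique(p$Prefix)), " prefixes, ", nrep,
        " in replicate groups, ", sum(p$Mask), " masked\n", sep = "")
})

#' MappingTable: source-to-target probe pairs
#'
#' Records the cg-number-prefix pairing between two platforms. A prefix with
#' j source and k target designs contributes j x k pairs. Each pair carries a
#' high-confidence flag set by
#' \code{\link{buildHighConfidenceMapping}} from paired same-sample
#' experiments; \code{\link{applyBiasFilter}} restricts to the flagged pairs.
#'
#' @slot sourcePlatform,targetPlatform platform labels.
#' @slot pairs data.frame with columns \code{Source_ID}, \code{Target_ID},
#'   \code{High_Confidence}.
#' @exportClass MappingTable
setClass("MappingTable",
    representation(sourcePlatform = "character",
                   targetPlatform = "character",
                   pairs = "data.frame"))

setValidity("MappingTable", function(object) {
    p <- object@pairs
    msg <- character()
    need <- c("Source_ID", "Target_ID", "High_Confidence")
    if (!all(need %in% names(p)))
        return(paste("pairs must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(p[, c("Source_ID", "Target_ID")]))
        msg <- c(msg, "(source, target) pairs must be unique")
    if (!is.logical(p$High_Confidence))
        msg <- c(msg, "High_Confidence must be logical")
    if (nrow(p) > 0L &&
        !all(probePrefix(p$Source_ID) == probePrefix(p$Target_ID)))
        msg <- c(msg, "paired IDs must share the same prefix")
    if (length(msg)) msg else TRUE
})

setMethod("show", "MappingTable", function(object) {
    p <- object@pairs
    cat("MappingTable ", object@sourcePlatform, " -> ",
        object@targetPlatform, ": ", nrow(p), " pairs (",
        length(unique(p$Source_ID)), " source, ",
        length(unique(p$Target_ID)), " target probes), ",
        sum(p$High_Confidence), " high-confidence\n", sep = "")
})

#' BetaMatrix: probes x samples methylation levels
#'
#' Beta values (per-probe methylation level, M/(M+U+offset)) lie in [0,1];
#' missing readings are \code{NA}. Rows are probes of one platform, columns
#' are samples. The \code{origin} slot records whether the values were
#' measured natively or produced by \code{\link{convertBeta}}; imputation
#' uses it for per-cell provenance.
#'
#' @slot platform platform label.
#' @slot beta numeric matrix with probe rownames and sample colnames.
#' @slot origin "measured" or "converted".
#' @exportClass BetaMatrix
setClass("BetaMatrix",
    representation(platform = "character", beta = "matrix",
                   origin = "character"))

setValidity("BetaMatrix", function(object) {
    b <- object@beta
    msg <- character()
    if (is.null(rownames(b)) || is.null(colnames(b)))
        return("beta matrix needs probe rownames and sample colnames")
    if (anyDuplicated(rownames(b)))
        msg <- c(msg, "probe IDs must be unique")
    v <- b[!is.na(b)]
    if (length(v) && (any(v < 0) || any(v > 1)))
        msg <- c(msg, "beta values must lie in [0, 1]")
    if (!object@origin %in% c("measured", "converted"))
        msg <- c(msg, "origin must be 'measured' or 'converted'")
    if (length(msg)) msg else TRUE
})

#' Construct a BetaMatrix
#'
#' @param platform platform label.
#' @param beta numeric matrix, probes in rows (rownames), samples in columns
#'   (colnames); values in [0,1] or \code{NA}.
#' @param origin provenance label for the non-missing cells.
#' @return a \linkS4class{BetaMatrix}.
#' @export
BetaMatrix <- function(platform, beta, origin = "measured") {
    new("BetaMatrix", platform = platform, beta = beta, origin = origin)
}

setMethod("show", "BetaMatrix", function(object) {
    b <- object@beta
    cat("BetaMatrix [", object@platform, "]: ", nrow(b), " probes x ",
        ncol(b), " samples (", object@origin, "), ",
        sum(is.na(b)), " missing cells\n", sep = "")
})

#' SignalFrame: per-probe raw signal records
#'
#' The per-sample signal table used for copy-number workflows: methylated
#' (M) and unmethylated (U) intensities, a detection p-value (significance
#' that the signal exceeds background; smaller = more reliable) and the
#' design-mask flag.
#'
#' @slot platform platform label.
#' @slot records data.frame with columns \code{Probe_ID}, \code{M}, \code{U},
#'   \code{Detection_P}, \code{Mask}.
#' @exportClass SignalFrame
setClass("SignalFrame",
    representation(platform = "character", records = "data.frame"))

setValidity("SignalFrame", function(object) {
    r <- object@records
    need <- c("Probe_ID", "M", "U", "Detection_P", "Mask")
    if (!all(need %in% names(r)))
        return(paste("records must have columns", paste(need, collapse = ", ")))
    msg <- character()
    if (anyDuplicated(r$Probe_ID))
        msg <- c(msg, "probe IDs must be unique")
    if (any(!is.finite(r$M)) || any(!is.finite(r$U)) ||
        any(r$M < 0) || any(r$U < 0))
        msg <- c(msg, "M and U must be finite and nonnegative")
    p <- r$Detection_P[!is.na(r$Detection_P)]
    if (length(p) && (any(p < 0) || any(p > 1)))
        msg <- c(msg, "Detection_P must lie in [0, 1] or be NA")
    if (!is.logical(r$Mask))
        msg <- c(msg, "Mask must be logical")
    if (length(msg)) msg else TRUE
})

#' Construct a SignalFrame
#'
#' @param platform platform label.
#' @param probeIDs probe IDs.
#' @param M,U methylated / unmethylated intensities (nonnegative, finite).
#' @param detectionP detection p-values in [0,1] or \code{NA}.
#' @param mask logical design-mask flags.
#' @return a \linkS4class{SignalFrame}.
#' @export
SignalFrame <- function(platform, probeIDs, M, U,
                        detectionP = rep(NA_real_, length(probeIDs)),
                        mask = rep(FALSE, length(probeIDs))) {
    new("SignalFrame", platform = platform,
        records = data.frame(Probe_ID = as.character(probeIDs),
                             M = as.numeric(M), U = as.numeric(U),
                             Detection_P = as.numeric(detectionP),
                             Mask = mask, stringsAsFactors = FALSE))
}

setMethod("show", "SignalFrame", function(object) {
    r <- object@records
    cat("SignalFrame [", object@platform, "]: ", nrow(r), " probes, ",
        sum(r$Mask), " masked, median total intensity ",
        round(stats::median(r$M + r$U), 1), "\n", sep = "")
})

#' PairedExperiment: one sample profiled on two platforms
#'
#' Beta readings of one biological sample (typically a cell line) assayed on
#' both the source and the target platform; a set of such pairs is the
#' empirical benchmark from which \code{\link{buildHighConfidenceMapping}}
#' derives platform-bias flags.
#'
#' @slot label experiment label, e.g. the cell-line name.
#' @slot sourceBetas,targetBetas named numeric vectors (names = probe IDs)
#'   of beta values in [0,1]; \code{NA} marks missing readings.
#' @exportClass PairedExperiment
setClass("PairedExperiment",
    representation(label = "character", sourceBetas = "numeric",
                   targetBetas = "numeric"))

setValidity("PairedExperiment", function(object) {
    msg <- character()
    for (nm in c("sourceBetas", "targetBetas")) {
        v <- slot(object, nm)
        if (is.null(names(v)))
            msg <- c(msg, paste(nm, "must be named by probe ID"))
        w <- v[!is.na(v)]
        if (length(w) && (any(w < 0) || any(w > 1)))
            msg <- c(msg, paste(nm, "must lie in [0, 1]"))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PairedExperiment
#'
#' @param label experiment label.
#' @param sourceBetas,targetBetas named numeric beta vectors on the source
#'   and target platforms.
#' @return a \linkS4class{PairedExperiment}.
#' @export
PairedExperiment <- function(label, sourceBetas, targetBetas) {
    new("PairedExperiment", label = label, sourceBetas = sourceBetas,
        targetBetas = targetBetas)
}

setMethod("show", "PairedExperiment", function(object) {
    cat("PairedExperiment '", object@label, "': ",
        sum(!is.na(object@sourceBetas)), " source / ",
        sum(!is.na(object@targetBetas)), " target readings\n", sep = "")
})

#' ImputationReference: tissue-indexed per-probe medians and SDs
#'
#' Summarizes a reference compendium for one target platform as per-tissue,
#' per-probe beta medians (the imputed value) and standard deviations (the
#' confidence metric: high-SD probes can be excluded from imputation).
#'
#' @slot platform platform label.
#' @slot medians,sds tissue x probe matrices (rownames = tissues, colnames =
#'   probe IDs).
#' @slot nSamples named integer vector of per-tissue sample counts.
#' @exportClass ImputationReference
setClass("ImputationReference",
    representation(platform = "character", medians = "matrix",
                   sds = "matrix", nSamples = "integer"))

setValidity("ImputationReference", function(object) {
    msg <- character()
    m <- object@medians; s <- object@sds
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("medians needs tissue rownames and probe colnames")
    if (!identical(dim(m), dim(s)) || !identical(dimnames(m), dimnames(s)))
        msg <- c(msg, "medians and sds must share dimensions and dimnames")
    v <- m[!is.na(m)]
    if (length(v) && (any(v < 0) || any(v > 1)))
        msg <- c(msg, "medians must lie in [0, 1]")
    w <- s[!is.na(s)]
    if (length(w) && any(w < 0))
        msg <- c(msg, "sds must be nonnegative")
    if (!all(rownames(m) %in% names(object@nSamples)))
        msg <- c(msg, "nSamples must cover every tissue")
    if (length(msg)) msg else TRUE
})

#' Construct an ImputationReference
#'
#' @param platform platform label.
#' @param medians,sds tissue x probe matrices of beta medians / SDs.
#' @param nSamples named integer per-tissue sample counts.
#' @return an \linkS4class{ImputationReference}.
#' @export
ImputationReference <- function(platform, medians, sds, nSamples) {
    ns <- as.integer(nSamples)
    names(ns) <- names(nSamples)
    new("ImputationReference", platform = platform, medians = medians,
        sds = sds, nSamples = ns)
}

setMethod("show", "ImputationReference", function(object) {
    cat("ImputationReference [", object@platform, "]: ",
        nrow(object@medians), " tissues x ", ncol(object@medians),
        " probes (", sum(object@nSamples), " reference samples)\n", sep = "")
})

#' ImputationResult: a completed beta matrix with provenance
#'
#' @slot betas completed \linkS4class{BetaMatrix}.
#' @slot provenance character matrix aligned to \code{betas}: "measured",
#'   "converted", "imputed", or "missing" for cells left unfilled.
#' @slot tissueUsed named character vector: the reference tissue used per
#'   sample.
#' @exportClass ImputationResult
setClass("ImputationResult",
    representation(betas = "BetaMatrix", provenance = "matrix",
                   tissueUsed = "character"))

setValidity("ImputationResult", function(object) {
    msg <- character()
    if (!identical(dim(object@provenance), dim(object@betas@beta)))
        msg <- c(msg, "provenance must be aligned to the beta matrix")
    if (!all(object@provenance %in%
             c("measured", "converted", "imputed", "missing")))
        msg <- c(msg, "provenance flags must be measured/converted/imputed/missing")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ImputationResult", function(object) {
    tab <- table(factor(object@provenance,
                        c("measured", "converted", "imputed", "missing")))
    cat("ImputationResult: ", nrow(object@betas@beta), " probes x ",
        ncol(object@betas@beta), " samples; cells: ",
        paste(names(tab), tab, sep = "=", collapse = ", "),
        "; tissues: ", paste(unique(object@tissueUsed), collapse = ", "),
        "\n", sep = "")
})
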