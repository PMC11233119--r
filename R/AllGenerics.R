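#' Accessors for methlift classes
#'
#' Slot access goes through these accessors: \code{platform} (every
#' platform-bound object), \code{probeIDs}, \code{sampleIDs} and
#' \code{betaValues} for \linkS4class{BetaMatrix}, \code{manifestProbes} for
#' \linkS4class{ProbeManifest}, \code{mappingPairs},
#' \code{sourcePlatform}/\code{targetPlatform} for
#' \linkS4class{MappingTable}, \code{signalRecords} for
#' \linkS4class{SignalFrame}, \code{tissues}, \code{referenceMedians},
#' \code{referenceSDs} for \linkS4class{ImputationReference}, and
#' \code{provenance}/\code{tissueUsed}/\code{resultBetas} for
#' \linkS4class{ImputationResult}.
#'
#' @param x the object.
#' @return the corresponding component (label, data.frame, matrix or vector).
#' @name accessors
#' @examples
#' m <- ProbeManifest("toy", c("cg01", "cg02"))
#' platform(m)
#' probeIDs(m)
NULL

#' @rdname accessors
#' @export
setGeneric("platform", function(x) standardGeneric("platform"))
#' @rdname accessors
#' @export
setGeneric("probeIDs", function(x) standardGeneric("probeIDs"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))
#' @rdname accessors
#' @export
setGeneric("manifestProbes", function(x) standardGeneric("manifestProbes"))
#' @rdname accessors
#' @export
setGeneric("mappingPairs", function(x) standardGeneric("mappingPairs"))
#' @rdname accessors
#' @export
setGeneric("sourcePlatform", function(x) standardGeneric("sourcePlatform"))
#' @rdname accessors
#' @export
setGeneric("targetPlatform", function(x) standardGeneric("targetPlatform"))
#' @rdname accessors
#' @export
setGeneric("signalRecords", function(x) standardGeneric("signalRecords"))
#' @rdname accessors
#' @export
setGeneric("tissues", function(x) standardGeneric("tissues"))
#' @rdname accessors
#' @export
setGeneric("referenceMedians", function(x) standardGeneric("referenceMedians"))
#' @rdname accessors
#' @export
setGeneric("referenceSDs", function(x) standardGeneric("referenceSDs"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("tissueUsed", function(x) standardGeneric("tissueUsed"))
#' @rdname accessors
#' @export
setGeneric("resultBetas", function(x) standardGeneric("resultBetas"))

#' @rdname accessors
#' @export
setMethod("platform", "ProbeManifest", function(x) x@platform)
#' @rdname accessors
#' @export
setMethod("platform", "BetaMatrix", function(x) x@platform)
#' @rdname accessors
#' @export
setMethod("platform", "SignalFrame", function(x) x@platform)
#' @rdname accessors
#' @export
setMethod("platform", "ImputationReference", function(x) x@platform)

#' @rdname accessors
#' @export
setMethod("probeIDs", "ProbeManifest", function(x) x@probes$Probe_ID)
#' @rdname accessors
#' @export
setMethod("probeIDs", "BetaMatrix", function(x) rownames(x@beta))
#' @rdname accessors
#' @export
setMethod("probeIDs", "SignalFrame", function(x) x@records$Probe_ID)
#' @rdname accessors
#' @export
setMethod("probeIDs", "ImputationReference", function(x) colnames(x@medians))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "BetaMatrix", function(x) colnames(x@beta))
#' @rdname accessors
#' @export
setMethod("betaValues", "BetaMatrix", function(x) x@beta)
#' @rdname accessors
#' @export
setMethod("manifestProbes", "ProbeManifest", function(x) x@probes)
#' @rdname accessors
#' @export
setMethod("mappingPairs", "MappingTable", function(x) x@pairs)
#' @rdname accessors
#' @export
setMethod("sourcePlatform", "MappingTable", function(x) x@sourcePlatform)
#' @rdname accessors
#' @export
setMethod("targetPlatform", "MappingTable", function(x) x@targetPlatform)
#' @rdname accessors
#' @export
setMethod("signalRecords", "SignalFrame", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("tissues", "ImputationReference", function(x) rownames(x@medians))
#' @rdname accessors
#' @export
setMethod("referenceMedians", "ImputationReference", function(x) x@medians)
#' @rdname accessors
#' @export
setMethod("referenceSDs", "ImputationReference", function(x) x@sds)
#' @rdname accessors
#' @export
setMethod("provenance", "ImputationResult", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("tissueUsed", "ImputationResult", function(x) x@tissueUsed)
#' @rdname accessors
#' @export
setMethod("resultBetas", "ImputationResult", function(x) x@betas)
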