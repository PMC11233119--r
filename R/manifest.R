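#' Group a manifest's probes by shared cg-number prefix
#'
#' Replicate probes are distinct designs (differing in strand, conversion,
#' chemistry or replicate index) that share one cg-number prefix and target
#' the same CpG. Every probe appears in exactly one group; singleton groups
#' are kept.
#'
#' @param m a \linkS4class{ProbeManifest}.
#' @return a named list, prefix -> character vector of full probe IDs.
#' @examples
#' m <- ProbeManifest("EPICv2", c("cg01_TC11", "cg01_BC11", "cg02"))
#' replicateGroups(m)
#' @export
replicateGroups <- function(m) {
    stopifnot(is(m, "ProbeManifest"))
    p <- manifestProbes(m)
    split(p$Probe_ID, factor(p$Prefix, levels = unique(p$Prefix)))
}

#' Build the source-to-target probe mapping for two platforms
#'
#' Pairs every source probe with every target probe sharing its cg-number
#' prefix (a prefix with j source and k target designs yields j x k pairs);
#' prefix equality is the sole criterion, suffix fields never need to match.
#' Source probes with no prefix match on the target platform are absent from
#' the mapping — downstream they become imputation candidates. All pairs
#' start with \code{High_Confidence = TRUE}; see
#' \code{\link{buildHighConfidenceMapping}} to set the flag empirically.
#'
#' @param source,target \linkS4class{ProbeManifest} objects.
#' @return a \linkS4class{MappingTable} ordered by (Source_ID, Target_ID).
#' @examples
#' src <- ProbeManifest("EPIC", "cg01")
#' tgt <- ProbeManifest("EPICv2", c("cg01_TC11", "cg01_BC11"))
#' mappingPairs(buildIdMapping(src, tgt))
#' @export
buildIdMapping <- function(source, target) {
    stopifnot(is(source, "ProbeManifest"), is(target, "ProbeManifest"))
    sp <- manifestProbes(source)[, c("Probe_ID", "Prefix")]
    tp <- manifestProbes(target)[, c("Probe_ID", "Prefix")]
    mrg <- merge(sp, tp, by = "Prefix",
                 suffixes = c(".src", ".tgt"), sort = FALSE)
    pairs <- data.frame(Source_ID = mrg$Probe_ID.src,
                        Target_ID = mrg$Probe_ID.tgt,
                        High_Confidence = rep(TRUE, nrow(mrg)),
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$Source_ID, pairs$Target_ID), , drop = FALSE]
    rownames(pairs) <- NULL
    new("MappingTable", sourcePlatform = platform(source),
        targetPlatform = platform(target), pairs = pairs)
}

#' Reverse a mapping table
#'
#' Swaps source and target roles; pair set and flags are preserved.
#'
#' @param mapping a \linkS4class{MappingTable}.
#' @return the reversed \linkS4class{MappingTable}.
#' @export
reverseMapping <- function(mapping) {
    stopifnot(is(mapping, "MappingTable"))
    p <- mappingPairs(mapping)
    pairs <- data.frame(Source_ID = p$Target_ID, Target_ID = p$Source_ID,
                        High_Confidence = p$High_Confidence,
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$Source_ID, pairs$Target_ID), , drop = FALSE]
    rownames(pairs) <- NULL
    new("MappingTable", sourcePlatform = targetPlatform(mapping),
        targetPlatform = sourcePlatform(mapping), pairs = pairs)
}

#' Read / write manifests and mapping tables as TSV
#'
#' Manifests are stored as tab-separated tables with header
#' \code{Probe_ID, Chemistry, Mask} (chemistry "I"/"II", mask
#' "TRUE"/"FALSE"); mapping tables with header
#' \code{Source_ID, Target_ID, High_Confidence}. Both are plain, lossless
#' and diff-friendly.
#'
#' @param path file path.
#' @param platform platform label for the manifest being read.
#' @param m a \linkS4class{ProbeManifest} to write.
#' @return \code{readManifest} returns a \linkS4class{ProbeManifest};
#'   writers return the path invisibly.
#' @name manifest-io
NULL

#' @rdname manifest-io
#' @export
readManifest <- function(path, platform) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(Probe_ID = "character",
                                          Chemistry = "character",
                                          Mask = "logical"))
    ProbeManifest(platform, d$Probe_ID, chemistry = d$Chemistry,
                  mask = d$Mask)
}

#' @rdname manifest-io
#' @export
writeManifest <- function(m, path) {
    stopifnot(is(m, "ProbeManifest"))
    utils::write.table(
        manifestProbes(m)[, c("Probe_ID", "Chemistry", "Mask")],
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname manifest-io
#' @param mapping a \linkS4class{MappingTable} to write.
#' @param sourcePlatform,targetPlatform platform labels for the mapping
#'   being read.
#' @export
readMappingTable <- function(path, sourcePlatform, targetPlatform) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(Source_ID = "character",
                                          Target_ID = "character",
                                          High_Confidence = "logical"))
    new("MappingTable", sourcePlatform = sourcePlatform,
        targetPlatform = targetPlatform, pairs = d)
}

#' @rdname manifest-io
#' @export
writeMappingTable <- function(mapping, path) {
    stopifnot(is(mapping, "MappingTable"))
    utils::write.table(mappingPairs(mapping), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
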