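#' Infer the closest reference tissue for a sample
#'
#' Matches a sample to the reference tissue whose median beta profile is
#' nearest in mean absolute deviation over the probes shared between the
#' sample and the reference. DNA methylation is dominated by tissue of
#' origin, so the nearest tissue profile is the best available context for
#' substituting completely missing probes. Ties are broken by reference
#' tissue order (first listed wins). The match needs a minimum overlap to
#' be stable; below \code{minOverlap} shared probes an error asks the user
#' to name the tissue explicitly.
#'
#' @param sampleBetas named numeric vector of beta values (names = probe
#'   IDs); \code{NA} entries are ignored.
#' @param ref an \linkS4class{ImputationReference}.
#' @param minOverlap minimum number of shared probes (default 100).
#' @return a tissue label from \code{tissues(ref)}.
#' @export
inferTissue <- function(sampleBetas, ref, minOverlap = 100L) {
    stopifnot(is(ref, "ImputationReference"))
    obs <- sampleBetas[!is.na(sampleBetas)]
    shared <- intersect(names(obs), probeIDs(ref))
    if (length(shared) < minOverlap)
        stop("only ", length(shared), " probes shared with the reference ",
             "(minimum ", minOverlap, "); specify the tissue explicitly")
    med <- referenceMedians(ref)[, shared, drop = FALSE]
    dev <- abs(sweep(med, 2L, obs[shared]))
    mad <- rowMeans(dev, na.rm = TRUE)
    tissues(ref)[which.min(mad)]        # which.min: first minimum wins
}

#' Probes eligible for imputation at an SD threshold
#'
#' The reference SD of a probe within a tissue gauges how trustworthy a
#' median substitution is: probes whose methylation varies strongly within
#' the tissue (e.g. with age or cell composition) make poor imputation
#' targets. Eligible probes are those with SD at or below the threshold.
#'
#' @param ref an \linkS4class{ImputationReference}.
#' @param tissue a tissue label in \code{tissues(ref)}.
#' @param threshold nonnegative SD cutoff; 0.08 is a validated practical
#'   choice for beta-scale references.
#' @return character vector of eligible probe IDs.
#' @export
filterReferenceBySd <- function(ref, tissue, threshold) {
    stopifnot(is(ref, "ImputationReference"))
    if (!tissue %in% tissues(ref))
        stop("tissue '", tissue, "' not in the reference")
    if (!is.numeric(threshold) || threshold < 0)
        stop("'threshold' must be nonnegative")
    sd <- referenceSDs(ref)[tissue, ]
    probeIDs(ref)[!is.na(sd) & sd <= threshold]
}

#' Impute completely missing probes from a tissue reference
#'
#' Fills target-platform probes that are absent from a beta matrix (typical
#' after \code{\link{convertBeta}} from a platform lacking them) with the
#' reference median beta of the matching tissue. The tissue is inferred per
#' sample with \code{\link{inferTissue}} unless named explicitly; inference
#' uses only that sample's own readings, so single-sample matrices work and
#' a sample's result never depends on other columns. When
#' \code{sdThreshold} is set, probes whose reference SD in the chosen
#' tissue exceeds it are left missing rather than imputed. Measured or
#' converted cells are never altered, so imputing twice equals imputing
#' once.
#'
#' @param b a \linkS4class{BetaMatrix} on the reference's platform.
#' @param ref an \linkS4class{ImputationReference}.
#' @param tissue optional tissue label applied to every sample; default
#'   infer per sample.
#' @param sdThreshold optional SD cutoff; probes above it stay missing.
#'   Unset imputes every eligible probe.
#' @param fillSporadic also fill \code{NA} cells of probes already present
#'   in \code{b} (off by default: those probes were assayed and their
#'   missingness may be informative).
#' @param manifest optional \linkS4class{ProbeManifest} defining the full
#'   platform probe universe; platform probes covered by neither \code{b}
#'   nor the reference are then included as missing rows and their count is
#'   reported.
#' @param minOverlap passed to \code{\link{inferTissue}}.
#' @return an \linkS4class{ImputationResult}: the completed matrix, a
#'   per-cell provenance matrix ("measured"/"converted"/"imputed"/
#'   "missing") and the tissue used per sample.
#' @export
imputeMissing <- function(b, ref, tissue = NULL, sdThreshold = NULL,
                          fillSporadic = FALSE, manifest = NULL,
                          minOverlap = 100L) {
    stopifnot(is(b, "BetaMatrix"), is(ref, "ImputationReference"))
    if (platform(b) != platform(ref))
        stop("beta matrix platform '", platform(b),
             "' does not match reference platform '", platform(ref), "'")
    if (!is.null(tissue) && !tissue %in% tissues(ref))
        stop("tissue '", tissue, "' not in the reference")
    vals <- betaValues(b)
    universe <- union(rownames(vals), probeIDs(ref))
    if (!is.null(manifest)) {
        stopifnot(is(manifest, "ProbeManifest"))
        universe <- union(rownames(vals), probeIDs(manifest))
        orphan <- setdiff(setdiff(universe, rownames(vals)), probeIDs(ref))
        if (length(orphan))
            message(length(orphan), " platform probe(s) absent from the ",
                    "reference; left missing")
    }
    newProbes <- sort(setdiff(universe, rownames(vals)))
    out <- rbind(vals,
                 matrix(NA_real_, length(newProbes), ncol(vals),
                        dimnames = list(newProbes, colnames(vals))))
    prov <- matrix("missing", nrow(out), ncol(out), dimnames = dimnames(out))
    prov[which(!is.na(vals), arr.ind = TRUE)] <- b@origin  # rows align
    tissueUsed <- character(ncol(out))
    names(tissueUsed) <- colnames(out)
    med <- referenceMedians(ref)
    for (j in seq_len(ncol(out))) {
        tj <- if (is.null(tissue))
            inferTissue(vals[, j], ref, minOverlap = minOverlap) else tissue
        tissueUsed[j] <- tj
        eligible <- if (is.null(sdThreshold)) probeIDs(ref)
                    else filterReferenceBySd(ref, tj, sdThreshold)
        fillRows <- intersect(newProbes, eligible)
        if (fillSporadic) {
            sporadic <- rownames(vals)[is.na(vals[, j])]
            fillRows <- c(fillRows, intersect(sporadic, eligible))
        }
        if (length(fillRows)) {
            out[fillRows, j] <- med[tj, fillRows]
            prov[fillRows, j] <- "imputed"
        }
    }
    new("ImputationResult",
        betas = BetaMatrix(platform(b), out, origin = b@origin),
        provenance = prov, tissueUsed = tissueUsed)
}

#' Read / write imputation reference panels
#'
#' The panel is a TSV with a \code{Probe_ID} column followed by per-tissue
#' \code{median__<tissue>} and \code{sd__<tissue>} column pairs, plus a
#' small YAML sidecar (same path with extension \code{.yaml}) recording
#' per-tissue sample counts.
#'
#' @param path TSV path; the sidecar is \code{<path>.yaml}.
#' @param platform platform label for the reference being read.
#' @param ref an \linkS4class{ImputationReference} to write.
#' @return \code{readImputationReference} returns an
#'   \linkS4class{ImputationReference}; the writer returns the path
#'   invisibly.
#' @name reference-io
NULL

#' @rdname reference-io
#' @export
readImputationReference <- function(path, platform) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    medCols <- grep("^median__", names(d), value = TRUE)
    tissueNames <- sub("^median__", "", medCols)
    med <- t(as.matrix(d[, paste0("median__", tissueNames), drop = FALSE]))
    sds <- t(as.matrix(d[, paste0("sd__", tissueNames), drop = FALSE]))
    dimnames(med) <- dimnames(sds) <- list(tissueNames, d$Probe_ID)
    side <- yaml::read_yaml(paste0(path, ".yaml"))
    ns <- unlist(side$n_samples)
    ImputationReference(platform, med, sds, ns[tissueNames])
}

#' @rdname reference-io
#' @export
writeImputationReference <- function(ref, path) {
    stopifnot(is(ref, "ImputationReference"))
    med <- referenceMedians(ref); sds <- referenceSDs(ref)
    d <- data.frame(Probe_ID = colnames(med), stringsAsFactors = FALSE)
    for (t in tissues(ref)) {
        d[[paste0("median__", t)]] <- med[t, ]
        d[[paste0("sd__", t)]] <- sds[t, ]
    }
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(list(platform = platform(ref),
                          n_samples = as.list(ref@nSamples)),
                     paste0(path, ".yaml"))
    invisible(path)
}
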