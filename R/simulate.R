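.tissuePool <- c("blood", "brain", "lung", "liver", "kidney", "colon",
                 "breast", "skin", "muscle", "endometrium", "prostate",
                 "pancreas")

# evaluate expr under a private RNG stream, restoring the caller's state
withSeed <- function(seed, expr) {
    hadSeed <- exists(".Random.seed", globalenv(), inherits = FALSE)
    old <- if (hadSeed) get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (hadSeed) assign(".Random.seed", old, globalenv())
        else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Configuration for the synthetic-fixture generators
#'
#' One object fixes everything the generators draw: platform composition,
#' replicate structure, tissue landscape, measurement noise and injected
#' platform bias. All generators are deterministic given (seed, config).
#'
#' Defaults describe the regime the package is validated in: per-cell
#' Gaussian noise of SD 0.02 on the beta scale (typical technical
#' replicate scatter for Infinium arrays), tissue median profiles at least
#' 0.1 apart in mean absolute deviation (distinct tissues differ far more
#' in practice), and a platform bias of 0.2 injected into 10\% of shared
#' probes — well above the 0.05 beta-difference threshold used for
#' high-confidence calling.
#'
#' @param seed integer seed.
#' @param nPrefixes number of distinct cg-number prefixes across platforms.
#' @param fracShared fraction of prefixes present on both platforms.
#' @param replicateDistribution named probability vector: replicate count
#'   ("1", "2", ...) -> probability, for the suffixed platform.
#' @param nTissues number of reference tissues.
#' @param tissueSeparation minimum pairwise mean absolute deviation between
#'   tissue median profiles.
#' @param noiseSd per-cell Gaussian noise SD on the beta scale (samples are
#'   clamped to [0,1]).
#' @param biasProbes fraction of shared prefixes receiving a fixed platform
#'   offset in paired experiments.
#' @param biasMagnitude absolute size of that offset.
#' @return a list of class \code{"SimulationConfig"}.
#' @export
simConfig <- function(seed = 1L, nPrefixes = 300L, fracShared = 0.8,
                      replicateDistribution = c("1" = 0.6, "2" = 0.3,
                                                "3" = 0.1),
                      nTissues = 5L, tissueSeparation = 0.1,
                      noiseSd = 0.02, biasProbes = 0.1,
                      biasMagnitude = 0.2) {
    stopifnot(fracShared >= 0, fracShared <= 1,
              biasProbes >= 0, biasProbes <= 1,
              noiseSd >= 0, nPrefixes >= 1, nTissues >= 1,
              abs(sum(replicateDistribution) - 1) < 1e-8,
              all(replicateDistribution >= 0),
              !is.null(names(replicateDistribution)))
    structure(list(seed = as.integer(seed), nPrefixes = as.integer(nPrefixes),
                   fracShared = fracShared,
                   replicateDistribution = replicateDistribution,
                   nTissues = as.integer(nTissues),
                   tissueSeparation = tissueSeparation, noiseSd = noiseSd,
                   biasProbes = biasProbes, biasMagnitude = biasMagnitude),
              class = "SimulationConfig")
}

.sampleSuffixes <- function(k, grammar = suffixGrammar()) {
    grid <- expand.grid(s = grammar$strand, c = grammar$conversion,
                        d = names(grammar$chemistry), r = 1:3,
                        stringsAsFactors = FALSE)
    pick <- grid[sample.int(nrow(grid), k), , drop = FALSE]
    paste0(pick$s, pick$c, pick$d, pick$r)
}

#' Generate a legacy/suffixed platform pair with known mapping
#'
#' Emulates an old-style platform (bare cg numbers, e.g. HM450/EPIC) and a
#' new-style platform (suffixed IDs, e.g. EPICv2) sharing
#' \code{fracShared} of their prefixes; the remaining prefixes are split
#' between the two platforms as platform-specific content. The suffixed
#' platform draws its per-prefix replicate count from
#' \code{replicateDistribution}. The returned ground-truth mapping
#' enumerates every prefix-matched pair.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param legacyName,suffixedName platform labels.
#' @return list with elements \code{legacy} and \code{suffixed}
#'   (\linkS4class{ProbeManifest}) and \code{mapping}
#'   (\linkS4class{MappingTable}).
#' @export
makePlatformPair <- function(cfg, legacyName = "legacy",
                             suffixedName = "suffixed") {
    stopifnot(inherits(cfg, "SimulationConfig"))
    withSeed(cfg$seed, {
        prefixes <- sprintf("cg%08d",
                            sample.int(99999999L, cfg$nPrefixes))
        nShared <- round(cfg$fracShared * cfg$nPrefixes)
        shared <- prefixes[seq_len(nShared)]
        rest <- prefixes[-seq_len(nShared)]
        legacyOnly <- rest[seq_len(floor(length(rest) / 2))]
        suffixedOnly <- setdiff(rest, legacyOnly)
        legacyIDs <- sort(c(shared, legacyOnly))
        legacy <- ProbeManifest(
            legacyName, legacyIDs,
            chemistry = sample(c("I", "II"), length(legacyIDs),
                               replace = TRUE, prob = c(0.2, 0.8)),
            mask = stats::runif(length(legacyIDs)) < 0.05)
        sufPrefixes <- c(shared, suffixedOnly)
        counts <- as.integer(names(cfg$replicateDistribution))[
            sample.int(length(cfg$replicateDistribution),
                       length(sufPrefixes), replace = TRUE,
                       prob = cfg$replicateDistribution)]
        ids <- unlist(lapply(seq_along(sufPrefixes), function(i) {
            paste0(sufPrefixes[i], "_", .sampleSuffixes(counts[i]))
        }))
        ids <- sort(ids)
        suffixed <- ProbeManifest(
            suffixedName, ids, mask = stats::runif(length(ids)) < 0.05)
        list(legacy = legacy, suffixed = suffixed,
             mapping = buildIdMapping(legacy, suffixed))
    })
}

#' Simulate a tissue-structured cohort and its imputation reference
#'
#' Tissue median beta profiles are drawn uniformly on [0,1] per cg-number
#' prefix (replicate probes of one prefix share a value, as they assay the
#' same CpG) and redrawn (deterministically) until every tissue pair is at
#' least \code{tissueSeparation} apart in mean absolute deviation over
#' probes. Cohort samples are tissue profile + truncated Gaussian noise.
#' The \linkS4class{ImputationReference} is computed from an independent
#' draw of \code{nReferenceSamples} per tissue (per-probe median and SD),
#' never from the cohort itself.
#'
#' Passing the \code{prefixProfiles} of a previous call as \code{profiles}
#' reuses the same underlying biology on another platform of the same
#' simulated pair: shared prefixes keep their tissue medians, prefixes not
#' covered get fresh draws (the separation guarantee applies only to fully
#' fresh draws).
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param manifest \linkS4class{ProbeManifest} of the platform to simulate.
#' @param nSamplesPerTissue cohort samples per tissue.
#' @param nReferenceSamples reference draws per tissue (default 500).
#' @param profiles optional tissue x prefix matrix of generating medians to
#'   reuse (rownames = tissues, colnames = prefixes).
#' @return list with \code{betas} (\linkS4class{BetaMatrix}),
#'   \code{tissueLabels} (named character, truth per sample),
#'   \code{reference} (\linkS4class{ImputationReference}), \code{profiles}
#'   (the generating tissue x probe median matrix) and
#'   \code{prefixProfiles} (the same keyed by prefix).
#' @export
simulateCohort <- function(cfg, manifest, nSamplesPerTissue = 3L,
                           nReferenceSamples = 500L, profiles = NULL) {
    stopifnot(inherits(cfg, "SimulationConfig"), is(manifest, "ProbeManifest"))
    probes <- probeIDs(manifest)
    prefixes <- manifestProbes(manifest)$Prefix
    uniq <- unique(prefixes)
    tissueNames <- if (is.null(profiles)) .tissuePool[seq_len(cfg$nTissues)]
                   else rownames(profiles)
    withSeed(cfg$seed + 1L, {
        drawPrefix <- function(who)
            matrix(stats::runif(length(tissueNames) * length(who)),
                   length(tissueNames),
                   dimnames = list(tissueNames, who))
        base <- NULL
        if (is.null(profiles)) {
            for (try in seq_len(100L)) {
                cand <- drawPrefix(uniq)
                expanded <- cand[, match(prefixes, uniq), drop = FALSE]
                d <- as.matrix(stats::dist(expanded,
                                           method = "manhattan")) /
                    length(probes)
                if (cfg$nTissues == 1L ||
                    min(d[upper.tri(d)]) >= cfg$tissueSeparation) {
                    base <- cand
                    break
                }
            }
            if (is.null(base))
                stop("could not draw tissue profiles ",
                     cfg$tissueSeparation,
                     " apart; lower 'tissueSeparation'")
        } else {
            known <- intersect(uniq, colnames(profiles))
            base <- cbind(profiles[, known, drop = FALSE],
                          drawPrefix(setdiff(uniq, known)))
            base <- base[, uniq, drop = FALSE]
        }
        profiles <- base[, match(prefixes, uniq), drop = FALSE]
        colnames(profiles) <- probes
        drawTissue <- function(t, n) {
            noise <- matrix(stats::rnorm(length(probes) * n,
                                         sd = cfg$noiseSd),
                            length(probes), n)
            pmin(pmax(profiles[t, ] + noise, 0), 1)
        }
        labels <- rep(tissueNames, each = nSamplesPerTissue)
        cohort <- do.call(cbind, lapply(tissueNames, drawTissue,
                                        n = nSamplesPerTissue))
        dimnames(cohort) <- list(probes,
                                 paste0(labels, "_s",
                                        seq_len(nSamplesPerTissue)))
        names(labels) <- colnames(cohort)
        med <- sds <- matrix(NA_real_, length(tissueNames), length(probes),
                             dimnames = list(tissueNames, probes))
        for (t in tissueNames) {
            draw <- drawTissue(t, nReferenceSamples)
            med[t, ] <- apply(draw, 1L, stats::median)
            sds[t, ] <- apply(draw, 1L, stats::sd)
        }
        list(betas = BetaMatrix(platform(manifest), cohort),
             tissueLabels = labels,
             reference = ImputationReference(
                 platform(manifest), med, sds,
                 stats::setNames(rep(as.integer(nReferenceSamples),
                                     length(tissueNames)), tissueNames)),
             profiles = profiles, prefixProfiles = base)
    })
}

#' Simulate paired same-sample experiments with injected platform bias
#'
#' Emulates the benchmark design where identical samples are profiled on
#' both platforms: per experiment, each prefix gets a true beta (uniform on
#' [0,1]); the source reading is truth + noise, the target reading is truth
#' + noise + a fixed platform offset for the biased prefixes. The offset
#' has magnitude \code{biasMagnitude} in every experiment; its sign points
#' toward the interior of [0,1] (negative when truth > 0.5) so clamping at
#' the boundaries never shrinks the injected difference. Bias is assigned
#' to a fraction \code{biasProbes} of the mapping's prefixes and returned
#' as ground truth.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param mapping the ground-truth \linkS4class{MappingTable}.
#' @param nExperiments number of paired experiments.
#' @return list with \code{experiments} (list of
#'   \linkS4class{PairedExperiment}), \code{biasedPrefixes} (character) and
#'   \code{biasedPairs} (logical aligned to the mapping's pairs).
#' @export
simulatePairedExperiments <- function(cfg, mapping, nExperiments = 5L) {
    stopifnot(inherits(cfg, "SimulationConfig"), is(mapping, "MappingTable"),
              nExperiments >= 1L)
    pairs <- mappingPairs(mapping)
    prefixes <- unique(probePrefix(pairs$Source_ID))
    withSeed(cfg$seed + 2L, {
        nBias <- round(cfg$biasProbes * length(prefixes))
        biased <- sample(prefixes, nBias)
        srcIDs <- unique(pairs$Source_ID)
        tgtIDs <- unique(pairs$Target_ID)
        srcPrefix <- probePrefix(srcIDs)
        tgtPrefix <- probePrefix(tgtIDs)
        clamp <- function(x) pmin(pmax(x, 0), 1)
        experiments <- lapply(seq_len(nExperiments), function(e) {
            truth <- stats::setNames(stats::runif(length(prefixes)),
                                     prefixes)
            offset <- ifelse(prefixes %in% biased,
                             ifelse(truth > 0.5, -cfg$biasMagnitude,
                                    cfg$biasMagnitude), 0)
            names(offset) <- prefixes
            src <- clamp(truth[srcPrefix] +
                         stats::rnorm(length(srcIDs), sd = cfg$noiseSd))
            tgt <- clamp(truth[tgtPrefix] + offset[tgtPrefix] +
                         stats::rnorm(length(tgtIDs), sd = cfg$noiseSd))
            PairedExperiment(paste0("experiment", e),
                             stats::setNames(src, srcIDs),
                             stats::setNames(tgt, tgtIDs))
        })
        list(experiments = experiments, biasedPrefixes = sort(biased),
             biasedPairs = probePrefix(pairs$Source_ID) %in% biased)
    })
}
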