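# Independent brute-force oracles. These deliberately avoid the package's
# parsing/mapping/aggregation code paths: IDs are split by substring, pairs
# are enumerated with double loops, aggregates recomputed cell by cell.

oracleParse <- function(id) {
    bits <- strsplit(id, "_", fixed = TRUE)[[1]]
    out <- list(prefix = bits[1], strand = NA_character_,
                conversion = NA_character_, chemistry = NA_character_,
                rep = NA_integer_)
    if (length(bits) == 2L) {
        s <- strsplit(bits[2], "")[[1]]
        out$strand <- s[1]
        out$conversion <- s[2]
        out$chemistry <- if (s[3] == "1") "I" else "II"
        out$rep <- as.integer(s[4])
    }
    out
}

oraclePrefix <- function(ids) {
    vapply(ids, function(id) strsplit(id, "_", fixed = TRUE)[[1]][1],
           character(1L), USE.NAMES = FALSE)
}

# all prefix-matched (source, target) pairs by double loop
oracleMappingPairs <- function(srcIDs, tgtIDs) {
    sp <- oraclePrefix(srcIDs)
    tp <- oraclePrefix(tgtIDs)
    out <- list()
    for (i in seq_along(srcIDs)) for (j in seq_along(tgtIDs)) {
        if (sp[i] == tp[j])
            out[[length(out) + 1L]] <- c(srcIDs[i], tgtIDs[j])
    }
    if (!length(out)) return(character(0))
    sort(vapply(out, paste, character(1L), collapse = "\r"))
}

pairKeys <- function(mapping) {
    p <- mappingPairs(mapping)
    sort(paste(p$Source_ID, p$Target_ID, sep = "\r"))
}

oracleMean <- function(values, masked = NULL, respectMask = FALSE) {
    if (respectMask && !is.null(masked)) values <- values[!masked]
    values <- values[!is.na(values)]
    if (!length(values)) return(NA_real_)
    sum(values) / length(values)
}

oracleBestDetection <- function(values, p, masked, ids) {
    keep <- which(!is.na(values) & !masked & !is.na(p))
    if (!length(keep)) return(oracleMean(values))
    keep <- keep[order(p[keep], ids[keep])]
    values[keep[1L]]
}

# per-cell recomputation of convertBeta by nested loops
oracleConvert <- function(vals, pairs, strategy = "mean", pmat = NULL,
                          maskmat = NULL) {
    pairs <- pairs[pairs$Source_ID %in% rownames(vals), , drop = FALSE]
    targets <- sort(unique(pairs$Target_ID))
    out <- matrix(NA_real_, length(targets), ncol(vals),
                  dimnames = list(targets, colnames(vals)))
    for (tgt in targets) {
        src <- sort(pairs$Source_ID[pairs$Target_ID == tgt])
        for (j in seq_len(ncol(vals))) {
            out[tgt, j] <- if (strategy == "mean")
                oracleMean(vals[src, j])
            else oracleBestDetection(vals[src, j], pmat[src, j],
                                     maskmat[src, j], src)
        }
    }
    out
}

# count per pair, per experiment list, of evaluable and agreeing experiments
oracleHighConfidence <- function(pairs, experiments, delta, minPairs) {
    flags <- logical(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
        agree <- 0L
        for (exp in experiments) {
            s <- exp@sourceBetas[pairs$Source_ID[k]]
            t <- exp@targetBetas[pairs$Target_ID[k]]
            if (!is.na(s) && !is.na(t) && abs(s - t) <= delta)
                agree <- agree + 1L
        }
        flags[k] <- agree >= minPairs
    }
    flags
}

# a tiny hand-built manifest trio used across tests
toyTrio <- function() {
    src <- ProbeManifest("A", c("cg00000001", "cg00000002", "cg00000003",
                                "cg00000009"))
    tgt <- ProbeManifest("B", c("cg00000001_TC11", "cg00000001_BC11",
                                "cg00000002_TC21", "cg00000003_TC11",
                                "cg00000003_TO12", "cg00000003_BC21",
                                "cg00000042"))
    list(src = src, tgt = tgt, mapping = buildIdMapping(src, tgt))
}
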