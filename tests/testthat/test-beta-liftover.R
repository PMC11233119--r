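randomBeta <- function(manifest, nSamples, missingFrac = 0,
                       origin = "measured") {
    ids <- probeIDs(manifest)
    m <- matrix(round(runif(length(ids) * nSamples), 4),
                length(ids), nSamples,
                dimnames = list(ids, paste0("s", seq_len(nSamples))))
    if (missingFrac > 0)
        m[runif(length(m)) < missingFrac] <- NA_real_
    BetaMatrix(platform(manifest), m, origin = origin)
}

test_that("mean aggregation matches the oracle over all small missingness patterns", {
    expect_equal(aggregateReplicates(c(0.2, 0.4), "mean"), 0.3)
    vals <- c(0.2, 0.5, 0.8)
    for (n in 1:3) {
        patterns <- expand.grid(rep(list(c(TRUE, FALSE)), n))
        for (k in seq_len(nrow(patterns))) {
            v <- vals[seq_len(n)]
            v[unlist(patterns[k, ])] <- NA_real_
            expect_equal(aggregateReplicates(v, "mean"), oracleMean(v))
        }
    }
    expect_true(is.na(aggregateReplicates(c(NA_real_, NA_real_), "mean")))
})

test_that("best-detection picks the argmin-p reading with documented fallbacks", {
    expect_equal(aggregateReplicates(c(0.2, 0.9), "best_detection",
                                     detectionP = c(0.5, 0.001)), 0.9)
    # masked candidates are excluded
    expect_equal(aggregateReplicates(c(0.2, 0.9), "best_detection",
                                     detectionP = c(0.5, 0.001),
                                     masked = c(FALSE, TRUE)), 0.2)
    # tie at smallest p: lexicographically lowest ID wins
    expect_equal(aggregateReplicates(c(0.2, 0.9), "best_detection",
                                     detectionP = c(0.01, 0.01),
                                     ids = c("cg2_b", "cg2_a")), 0.9)
    # no usable candidate: fall back to mean of non-missing values
    expect_equal(aggregateReplicates(c(0.2, 0.6), "best_detection",
                                     detectionP = c(NA, NA)), 0.4)
    expect_error(aggregateReplicates(c(0.2), "best_detection"), "detectionP")
    expect_error(aggregateReplicates(numeric(0), "mean"), "nonempty")
})

test_that("replicate-free to replicated conversion broadcasts rows verbatim", {
    src <- ProbeManifest("A", "cg00000001")
    tgt <- ProbeManifest("B", c("cg00000001_TC11", "cg00000001_BC11"))
    map <- buildIdMapping(src, tgt)
    b <- BetaMatrix("A", matrix(c(0.12, 0.98), 1, 2,
                                dimnames = list("cg00000001", c("s1", "s2"))))
    out <- betaValues(convertBeta(b, map))
    expect_identical(out["cg00000001_TC11", ], betaValues(b)[1, ])
    expect_identical(out["cg00000001_BC11", ], betaValues(b)[1, ])
})

test_that("identity mapping returns the input values under both strategies", {
    m <- ProbeManifest("A", sprintf("cg%08d", 1:15))
    map <- buildIdMapping(m, m)
    set.seed(3)
    b <- randomBeta(m, 3, missingFrac = 0.1)
    sf <- SignalFrame("A", probeIDs(m), M = runif(15, 0, 5000),
                      U = runif(15, 0, 5000), detectionP = runif(15))
    for (strat in c("mean", "best_detection")) {
        out <- convertBeta(b, map, strat, signal = sf)
        expect_equal(betaValues(out)[probeIDs(b), ], betaValues(b))
    }
})

test_that("conversion equals per-cell brute-force recomputation", {
    set.seed(11)
    for (rep in 1:5) {
        pair <- makePlatformPair(simConfig(seed = rep, nPrefixes = 20))
        b <- randomBeta(pair$suffixed, 3, missingFrac = 0.15)
        map <- buildIdMapping(pair$suffixed, pair$legacy)
        ids <- probeIDs(pair$suffixed)
        sf <- SignalFrame("suffixed", ids, M = runif(length(ids), 0, 5000),
                          U = runif(length(ids), 0, 5000),
                          detectionP = round(runif(length(ids)), 3),
                          mask = runif(length(ids)) < 0.2)
        dm <- list(
            p = matrix(signalRecords(sf)$Detection_P, length(ids), 3,
                       dimnames = list(ids, sampleIDs(b))),
            mask = matrix(signalRecords(sf)$Mask, length(ids), 3,
                          dimnames = list(ids, sampleIDs(b))))
        expect_equal(betaValues(convertBeta(b, map, "mean")),
                     oracleConvert(betaValues(b), mappingPairs(map), "mean"))
        expect_equal(betaValues(convertBeta(b, map, "best_detection",
                                            signal = sf)),
                     oracleConvert(betaValues(b), mappingPairs(map),
                                   "best_detection", dm$p, dm$mask))
    }
})

test_that("round trip restores one-to-one probes and output stays in source range", {
    set.seed(5)
    for (rep in 1:5) {
        pair <- makePlatformPair(simConfig(seed = rep + 20, nPrefixes = 40))
        fwd <- buildIdMapping(pair$legacy, pair$suffixed)
        bwd <- buildIdMapping(pair$suffixed, pair$legacy)
        b <- randomBeta(pair$legacy, 2)
        there <- convertBeta(b, fwd)
        back <- convertBeta(there, bwd)
        # one-to-one subset: prefixes with exactly one probe on each side
        p <- mappingPairs(fwd)
        oneSrc <- names(which(table(p$Source_ID) == 1))
        oneTgt <- names(which(table(p$Target_ID) == 1))
        oneToOne <- p$Source_ID[p$Source_ID %in% oneSrc &
                                p$Target_ID %in% oneTgt]
        expect_gt(length(oneToOne), 0)
        expect_identical(betaValues(back)[oneToOne, ],
                         betaValues(b)[oneToOne, ])
        # every converted value lies within its source feed's range
        pb <- p[p$Source_ID %in% probeIDs(b), ]
        for (tgt in sample(unique(pb$Target_ID), 20)) {
            src <- pb$Source_ID[pb$Target_ID == tgt]
            rng <- range(betaValues(b)[src, ])
            v <- betaValues(there)[tgt, ]
            expect_true(all(v >= rng[1] - 1e-12 & v <= rng[2] + 1e-12))
        }
        # samples preserved; replicate-richer platform has at least as many rows
        expect_identical(sampleIDs(there), sampleIDs(b))
        shared <- intersect(oraclePrefix(probeIDs(pair$legacy)),
                            oraclePrefix(probeIDs(pair$suffixed)))
        expect_gte(nrow(betaValues(there)),
                   sum(oraclePrefix(probeIDs(b)) %in% shared))
    }
})

test_that("conversion rejects platform mismatches and skips unknown sources", {
    trio <- toyTrio()
    b <- BetaMatrix("Z", matrix(0.5, 1, 1,
                                dimnames = list("cg00000001", "s1")))
    expect_error(convertBeta(b, trio$mapping), "platform")
    b2 <- BetaMatrix("A", matrix(0.5, 1, 1,
                                 dimnames = list("cg00000001", "s1")))
    expect_message(out <- convertBeta(b2, trio$mapping), "skipped")
    expect_setequal(probeIDs(out), c("cg00000001_TC11", "cg00000001_BC11"))
    expect_error(convertBeta(b2, trio$mapping, "best_detection"), "signal")
    expect_error(convertBeta(b2, trio$mapping, respectMask = TRUE), "signal")
})

test_that("respectMask drops masked readings from mean aggregation", {
    src <- ProbeManifest("A", c("cg00000001_TC11", "cg00000001_BC11"))
    tgt <- ProbeManifest("B", "cg00000001")
    map <- buildIdMapping(src, tgt)
    b <- BetaMatrix("A", matrix(c(0.2, 0.8), 2, 1,
                    dimnames = list(probeIDs(src), "s1")))
    sf <- SignalFrame("A", probeIDs(src), M = c(1, 1), U = c(1, 1),
                      mask = c(TRUE, FALSE))
    expect_equal(betaValues(convertBeta(b, map, "mean"))[1, 1], 0.5)
    expect_equal(betaValues(convertBeta(b, map, "mean", signal = sf,
                                        respectMask = TRUE))[1, 1], 0.8)
})
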