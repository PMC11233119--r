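toyReference <- function(nProbes = 12, tissues = c("blood", "brain"),
                         seed = 1) {
    set.seed(seed)
    probes <- sprintf("cg%08d", seq_len(nProbes))
    med <- matrix(round(runif(length(tissues) * nProbes), 3),
                  length(tissues), nProbes,
                  dimnames = list(tissues, probes))
    sds <- matrix(round(runif(length(tissues) * nProbes, 0, 0.15), 3),
                  length(tissues), nProbes,
                  dimnames = list(tissues, probes))
    ImputationReference("toy", med, sds,
                        setNames(rep(50L, length(tissues)), tissues))
}

test_that("tissue inference returns the zero-distance match and first tie", {
    ref <- toyReference(nProbes = 150)
    blood <- referenceMedians(ref)["blood", ]
    expect_equal(inferTissue(blood, ref), "blood")
    # two identical profiles: first listed wins
    med <- referenceMedians(ref)
    med["brain", ] <- med["blood", ]
    twin <- ImputationReference("toy", med, referenceSDs(ref),
                                c(blood = 50L, brain = 50L))
    expect_equal(inferTissue(blood, twin), "blood")
    expect_error(inferTissue(blood[1:10], ref), "specify the tissue")
})

test_that("noisy samples recover their tissue when profiles are separated", {
    cfg <- simConfig(seed = 23, nPrefixes = 150, nTissues = 4,
                     tissueSeparation = 0.1, noiseSd = 0.02)
    pair <- makePlatformPair(cfg)
    co <- simulateCohort(cfg, pair$legacy, nSamplesPerTissue = 25,
                         nReferenceSamples = 200)
    vals <- betaValues(co$betas)
    hits <- vapply(seq_len(ncol(vals)), function(j)
        inferTissue(vals[, j], co$reference), character(1))
    expect_identical(unname(hits), unname(co$tissueLabels))
})

test_that("SD-based eligibility equals a brute-force scan and is monotone", {
    ref <- toyReference()
    sds <- referenceSDs(ref)["blood", ]
    for (thr in c(0, 0.05, 0.08, 0.12, 1)) {
        expect_setequal(filterReferenceBySd(ref, "blood", thr),
                        names(sds)[sds <= thr])
    }
    sizes <- vapply(seq(0, 0.2, by = 0.01), function(thr)
        length(filterReferenceBySd(ref, "blood", thr)), numeric(1))
    expect_true(!is.unsorted(sizes))
    expect_error(filterReferenceBySd(ref, "bone", 0.1), "not in the reference")
    expect_error(filterReferenceBySd(ref, "blood", -1), "nonnegative")
})

test_that("a complete matrix is returned unchanged with zero imputed cells", {
    ref <- toyReference()
    b <- BetaMatrix("toy", matrix(referenceMedians(ref)["blood", ],
                                  dimnames = list(probeIDs(ref), "s1")),
                    origin = "measured")
    res <- imputeMissing(b, ref, tissue = "blood")
    expect_identical(betaValues(resultBetas(res)), betaValues(b))
    expect_true(all(provenance(res) == "measured"))
})

test_that("SD threshold controls exactly which absent probes are imputed", {
    ref <- toyReference()
    sds <- c(rep(0.02, 7), rep(0.2, 3), 0.01, 0.01)
    refSds <- referenceSDs(ref)
    refSds["blood", ] <- sds
    ref2 <- ImputationReference("toy", referenceMedians(ref), refSds,
                                c(blood = 50L, brain = 50L))
    # sample measures only the last 2 probes; 10 absent, 3 with sd > 0.08
    present <- probeIDs(ref2)[11:12]
    b <- BetaMatrix("toy", matrix(0.5, 2, 2,
                    dimnames = list(present, c("s1", "s2"))))
    res <- imputeMissing(b, ref2, tissue = "blood", sdThreshold = 0.08)
    expect_equal(sum(provenance(res) == "imputed"), 7 * 2)
    expect_equal(sum(is.na(betaValues(resultBetas(res)))), 3 * 2)
    # imputed cells carry the tissue median of their probe
    imp <- which(provenance(res) == "imputed", arr.ind = TRUE)
    vals <- betaValues(resultBetas(res))
    expect_identical(
        unname(vals[imp]),
        unname(referenceMedians(ref2)["blood", rownames(vals)[imp[, 1]]]))
})

test_that("zero-noise deletion is restored exactly by infer-then-impute", {
    cfg <- simConfig(seed = 31, nPrefixes = 200, noiseSd = 0,
                     nTissues = 3)
    pair <- makePlatformPair(cfg)
    co <- simulateCohort(cfg, pair$legacy, nSamplesPerTissue = 1,
                         nReferenceSamples = 50)
    full <- betaValues(co$betas)
    set.seed(31)
    deleted <- sample(rownames(full), 50)
    b <- BetaMatrix("legacy", full[setdiff(rownames(full), deleted), ,
                                   drop = FALSE])
    res <- imputeMissing(b, co$reference)   # tissue inferred per sample
    expect_identical(unname(tissueUsed(res)), unname(co$tissueLabels))
    out <- betaValues(resultBetas(res))
    expect_equal(out[deleted, ], full[deleted, ], tolerance = 1e-12)
    expect_true(all(provenance(res)[deleted, ] == "imputed"))
})

test_that("imputation is idempotent and never touches present cells", {
    ref <- toyReference()
    set.seed(4)
    b <- BetaMatrix("toy",
                    matrix(runif(8 * 2), 8, 2,
                           dimnames = list(probeIDs(ref)[1:8],
                                           c("s1", "s2"))))
    res1 <- imputeMissing(b, ref, tissue = "brain")
    res2 <- imputeMissing(resultBetas(res1), ref, tissue = "brain")
    expect_identical(betaValues(resultBetas(res2)),
                     betaValues(resultBetas(res1)))
    expect_identical(betaValues(resultBetas(res1))[probeIDs(b), ],
                     betaValues(b))
})

test_that("single-column imputation is independent of other columns", {
    cfg <- simConfig(seed = 77, nPrefixes = 150, nTissues = 2)
    pair <- makePlatformPair(cfg)
    co <- simulateCohort(cfg, pair$legacy, nSamplesPerTissue = 3,
                         nReferenceSamples = 50)
    full <- betaValues(co$betas)
    set.seed(77)
    keep <- sample(rownames(full), nrow(full) - 30)
    b <- BetaMatrix("legacy", full[keep, ])
    whole <- imputeMissing(b, co$reference)
    for (perm in list(ncol(full):1, sample(ncol(full)))) {
        permuted <- imputeMissing(
            BetaMatrix("legacy", full[keep, perm]), co$reference)
        expect_identical(betaValues(resultBetas(permuted))[, sampleIDs(b)],
                         betaValues(resultBetas(whole)))
    }
    one <- imputeMissing(
        BetaMatrix("legacy", full[keep, 1, drop = FALSE]), co$reference)
    expect_identical(betaValues(resultBetas(one))[, 1],
                     betaValues(resultBetas(whole))[, 1])
})

test_that("provenance distinguishes converted from measured input", {
    ref <- toyReference()
    b <- BetaMatrix("toy", matrix(0.4, 2, 1,
                    dimnames = list(probeIDs(ref)[1:2], "s1")),
                    origin = "converted")
    res <- imputeMissing(b, ref, tissue = "blood")
    expect_true(all(provenance(res)[probeIDs(b), ] == "converted"))
    expect_true(all(provenance(res)[probeIDs(ref)[3:12], ] == "imputed"))
})

test_that("sporadic missing cells are filled only on request", {
    ref <- toyReference()
    m <- matrix(c(0.3, NA, 0.7, 0.1), 2, 2,
                dimnames = list(probeIDs(ref)[1:2], c("s1", "s2")))
    b <- BetaMatrix("toy", m)
    res <- imputeMissing(b, ref, tissue = "blood")
    expect_true(is.na(betaValues(resultBetas(res))["cg00000002", "s1"]))
    expect_equal(provenance(res)["cg00000002", "s1"], "missing")
    res2 <- imputeMissing(b, ref, tissue = "blood", fillSporadic = TRUE)
    expect_equal(betaValues(resultBetas(res2))["cg00000002", "s1"],
                 referenceMedians(ref)["blood", "cg00000002"])
})

test_that("platform and tissue mismatches raise argument errors", {
    ref <- toyReference()
    b <- BetaMatrix("other", matrix(0.5, 1, 1,
                    dimnames = list(probeIDs(ref)[1], "s1")))
    expect_error(imputeMissing(b, ref), "platform")
    b2 <- BetaMatrix("toy", matrix(0.5, 1, 1,
                     dimnames = list(probeIDs(ref)[1], "s1")))
    expect_error(imputeMissing(b2, ref, tissue = "bone"), "not in the reference")
    # manifest probes unknown to the reference are reported and left missing
    man <- ProbeManifest("toy", c(probeIDs(ref), "cg99999999"))
    expect_message(res <- imputeMissing(b2, ref, tissue = "blood",
                                        manifest = man, minOverlap = 1),
                   "absent from the reference")
    expect_true(is.na(betaValues(resultBetas(res))["cg99999999", 1]))
})
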