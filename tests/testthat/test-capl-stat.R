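# The statistic T, its TDT equivalence on complete triads, antisymmetry,
# and the bootstrap variance machinery.

test_that("family contributions follow observed-minus-expected arithmetic", {
    u <- FamilyUnit("F", father = 1L, mother = 2L, affectedSibs = 3L,
                    designTag = "triad")
    g <- c(1L, 2L, 2L)
    fw <- familyWeights(u, g, prior = 1, p = 0.5)
    expect_equal(familyContribution(u, g, fw), 2 - 1.5)

    ctrl <- FamilyUnit("U", unaffectedSibs = 1L,
                       designTag = "control_singleton")
    fwc <- familyWeights(ctrl, 1L, prior = 1, p = 0.5)
    expect_equal(familyContribution(ctrl, 1L, fwc), 0)

    cs <- FamilyUnit("U", affectedSibs = 1L, designTag = "case_singleton")
    fws <- familyWeights(cs, 2L, prior = 1, p = 0.5)
    oracle <- familyWeightsOracle(NA, NA, 2L, 1, 0.5, c(.25, .5, .25))
    eOracle <- sum(apply(oracle, 2, sum) * rowSums(matingTypes()) / 2)
    expect_equal(familyContribution(cs, 2L, fws), 2 - eOracle,
                 tolerance = 1e-12)
})

test_that("T equals the TDT count oracle on complete triads", {
    for (s in 1:10) {
        cfg <- simConfig(counts = data.frame(cases = 0, controls = 0,
                                             triads = 120, multiplex = 0),
                         nMarkers = 2, fst = 0, seed = 400 + s)
        st <- simulateStudy(cfg)
        u <- familyUnits(st)
        g <- genotypes(st)[1, ]
        em <- runEm(u, g, matrix(1, length(u), 1), 1)
        bc <- tdtCounts(u, g)
        expect_equal(caplT(em), unname((bc["b"] - bc["c"]) / 2),
                     tolerance = 1e-9)
    }
})

test_that("recoding the counted allele negates T and preserves the test", {
    cfg <- simConfig(counts = data.frame(cases = 25, controls = 25,
                                         triads = 12, multiplex = 12),
                     nMarkers = 30, fst = 0, seed = 77)
    st <- simulateStudy(cfg)
    u <- familyUnits(st)
    g <- genotypes(st)[4, ]
    res <- caplMarkerTest(u, g, K = 1, B = 60, seed = 5)
    resFlip <- caplMarkerTest(u, 2L - g, K = 1, B = 60, seed = 5)
    expect_equal(resFlip$T, -res$T, tolerance = 1e-9)
    expect_equal(resFlip$bootSd, res$bootSd, tolerance = 1e-9)
    expect_equal(abs(resFlip$zScore), abs(res$zScore), tolerance = 1e-9)
    expect_equal(resFlip$pValue, res$pValue, tolerance = 1e-9)
    expect_equal(resFlip$pHat[[1]], 1 - res$pHat[[1]], tolerance = 1e-6)
})

test_that("bootstrap is deterministic in the seed", {
    cfg <- simConfig(counts = data.frame(cases = 20, controls = 20,
                                         triads = 10, multiplex = 10),
                     nMarkers = 25, fst = 0.1, seed = 31)
    st <- simulateStudy(cfg)
    u <- familyUnits(st)
    d <- ibsDistanceMatrix(st)$d
    g <- genotypes(st)[3, ]
    b1 <- bootstrapVariance(u, g, d, K = 2, B = 40, seed = 9)
    b2 <- bootstrapVariance(u, g, d, K = 2, B = 40, seed = 9)
    expect_identical(b1, b2)
    b3 <- bootstrapVariance(u, g, d, K = 2, B = 40, seed = 10)
    expect_false(isTRUE(all.equal(b1$bootSd, b3$bootSd)))
})

test_that("identical homozygous units give exactly zero bootstrap variance", {
    g <- rep(2L, 6)
    units <- lapply(1:6, function(i)
        FamilyUnit(sprintf("U%d", i), affectedSibs = i,
                   designTag = "case_singleton"))
    bv <- bootstrapVariance(units, g, K = 1, B = 20, seed = 2)
    expect_equal(bv$bootSd, 0)
    expect_true(bv$degenerate)
    # and the full test reports the degenerate/monomorphic status
    res <- caplMarkerTest(units, g, K = 1, B = 20, seed = 2)
    expect_equal(res$status, "monomorphic")
})

test_that("the normal reference converts z-scores to two-sided p-values", {
    # via a marker whose statistic is forced to zero: p must be 1
    u <- list(FamilyUnit("F", father = 1L, mother = 2L, affectedSibs = 3L,
                         designTag = "triad"),
              FamilyUnit("G", father = 4L, mother = 5L, affectedSibs = 6L,
                         designTag = "triad"))
    g <- c(2L, 0L, 1L, 0L, 2L, 1L)   # both children forced heterozygous
    res <- caplMarkerTest(u, g, K = 1, B = 30, seed = 4)
    expect_equal(res$T, 0)
    if (res$status == "ok") expect_equal(res$pValue, 1)
    expect_equal(2 * (1 - pnorm(1.959964)), 0.05, tolerance = 1e-6)
})

test_that("bootstrap SD tracks the Monte-Carlo sampling SD of T", {
    # scaled from the stated design for runtime: null triads, the bootstrap
    # estimate from one dataset must land within 25% of the empirical SD of
    # T over independently simulated datasets
    nFam <- 120; nData <- 250
    Ts <- vapply(seq_len(nData), function(s) {
        cfg <- simConfig(counts = data.frame(cases = 0, controls = 0,
                                             triads = nFam, multiplex = 0),
                         nMarkers = 2, fst = 0, causalIndex = 2,
                         seed = 9000 + s)
        st <- simulateStudy(cfg)
        u <- familyUnits(st)
        g <- genotypes(st)[1, ]
        em <- runEm(u, g, matrix(1, length(u), 1), 1)
        caplT(em)
    }, numeric(1))
    mcSd <- sd(Ts)
    cfg <- simConfig(counts = data.frame(cases = 0, controls = 0,
                                         triads = nFam, multiplex = 0),
                     nMarkers = 2, fst = 0, causalIndex = 2, seed = 1234)
    st <- simulateStudy(cfg)
    u <- familyUnits(st)
    bv <- bootstrapVariance(u, genotypes(st)[1, ], K = 1, B = 120, seed = 7)
    expect_lt(abs(bv$bootSd - mcSd) / mcSd, 0.25)
})
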