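# Per-marker EM: single-family posteriors against exhaustive enumeration,
# fixed points, likelihood monotonicity and label equivariance.

test_that("family weights are degenerate when both parents are observed", {
    u <- FamilyUnit("F", father = 1L, mother = 2L, affectedSibs = 3L,
                    designTag = "triad")
    fw <- familyWeights(u, c(1L, 2L, 2L), prior = 1, p = 0.4)
    expect_equal(dim(fw$w), c(1L, 6L, 1L))
    expect_equal(fw$w[1, , 1], c(0, 0, 0, 0, 1, 0))   # mating type (1,2)
    expect_equal(fw$origin, 1)
})

test_that("single-family weights match the exhaustive oracle", {
    z <- c(0.25, 0.5, 0.25)
    # case singleton, one subpopulation: 6-term mating-type enumeration
    u <- FamilyUnit("U", affectedSibs = 1L, designTag = "case_singleton")
    fw <- familyWeights(u, 2L, prior = 1, p = 0.5)
    oracle <- familyWeightsOracle(NA, NA, 2L, prior = 1, p = 0.5, z = z)
    expect_lt(max(abs(fw$w[1, , 1] - oracle[1, , 1])), 1e-12)

    # two affected sibs, one observed parent, two subpopulations
    u2 <- FamilyUnit("F", father = 1L, affectedSibs = c(2L, 3L),
                     designTag = "other")
    pri <- c(0.7, 0.3); p <- c(0.2, 0.6)
    fw2 <- familyWeights(u2, c(1L, 1L, 2L), prior = pri, p = p, z = z)
    or2 <- familyWeightsOracle(1L, NA, c(1L, 2L), prior = pri, p = p, z = z)
    expect_lt(max(abs(fw2$w - or2)), 1e-12)
    expect_equal(sum(fw2$w), 1)

    # control singleton with missing genotype: prior-only posterior
    u3 <- FamilyUnit("U", unaffectedSibs = 1L,
                     designTag = "control_singleton")
    fw3 <- familyWeights(u3, NA_integer_, prior = pri, p = p)
    or3 <- familyWeightsOracle(NA, NA, integer(0), prior = pri, p = p, z = z)
    expect_lt(max(abs(fw3$w[, , 1] - or3[, , 1])), 1e-12)

    # impossible configuration: excluded with a warning
    u4 <- FamilyUnit("F", father = 1L, mother = 2L, affectedSibs = 3L)
    expect_warning(out <- familyWeights(u4, c(2L, 2L, 1L), 1, 0.5),
                   "excluded")
    expect_null(out)
})

test_that("E-step sufficient statistics match weighted enumeration sums", {
    set.seed(11)
    units <- list(
        FamilyUnit("F1", father = 1L, mother = 2L, affectedSibs = 3L,
                   designTag = "triad"),
        FamilyUnit("F2", father = 4L, mother = 5L,
                   affectedSibs = c(6L, 7L), designTag = "multiplex"),
        FamilyUnit("U1", affectedSibs = 8L, designTag = "case_singleton"))
    g <- c(1L, 1L, 2L, NA, 1L, 1L, 2L, 0L)
    pri <- matrix(c(.8, .2, .5, .5, .1, .9), 3, 2, byrow = TRUE)
    p <- c(0.3, 0.7); z <- c(0.2, 0.5, 0.3)
    st <- emEStep(units, g, pri, p, z)

    a <- rowSums(matingTypes())
    SpO <- c(0, 0); NO <- c(0, 0); SzO <- c(0, 0, 0); llO <- 0; eO <- NULL
    specs <- list(list(gf = 1L, gm = 1L, sibs = 2L),
                  list(gf = NA, gm = 1L, sibs = c(1L, 2L)),
                  list(gf = NA, gm = NA, sibs = 0L))
    for (i in 1:3) {
        s <- specs[[i]]
        w <- familyWeightsOracle(s$gf, s$gm, s$sibs, pri[i, ], p, z)
        for (k in 1:2) {
            SpO[k] <- SpO[k] + sum(w[k, , ] * a)
            NO[k] <- NO[k] + sum(w[k, , ])
        }
        if (length(s$sibs) == 2L)
            for (j in 1:3) SzO[j] <- SzO[j] + sum(w[, , j])
    }
    expect_equal(st$Sp, SpO, tolerance = 1e-10)
    expect_equal(st$N, NO, tolerance = 1e-10)
    expect_equal(st$Sz, SzO, tolerance = 1e-10)
    expect_equal(rowSums(st$origin), rep(1, 3))

    upd <- emMStep(st, p, z)
    expect_equal(upd$p, pmin(pmax(SpO / (4 * NO), 1e-6), 1 - 1e-6))
    expect_equal(upd$z, SzO / sum(SzO))
})

test_that("R reference E/M steps reproduce the compiled EM trajectory", {
    cfg <- simConfig(counts = data.frame(cases = 15, controls = 15,
                                         triads = 8, multiplex = 8),
                     nMarkers = 4, fst = 0.1, seed = 5)
    st <- simulateStudy(cfg)
    u <- familyUnits(st)
    g <- genotypes(st)[2, ]
    lab <- S4Vectors::metadata(st)$truth$subpop
    pri <- familyOriginPriors(lab, u, 1)
    em <- runEm(u, g, pri, 1, maxIter = 3L, tol = 0)
    p <- mean(g, na.rm = TRUE) / 2; z <- c(.25, .5, .25)
    ll <- numeric(3)
    for (it in 1:3) {
        s <- emEStep(u, g, pri, p, z)
        ll[it] <- s$loglik
        upd <- emMStep(s, p, z)
        p <- upd$p; z <- upd$z
    }
    expect_equal(em$model$p, p, tolerance = 1e-12)
    expect_equal(em$model$z, z, tolerance = 1e-12)
    expect_equal(em$model$loglikTrace, ll, tolerance = 1e-10)
})

test_that("K=1 case/control EM fixed point is the sample allele frequency", {
    g <- c(rep(2L, 10), rep(1L, 20), rep(0L, 70))
    units <- lapply(seq_along(g), function(i)
        FamilyUnit(sprintf("U%d", i),
                   unaffectedSibs = i, designTag = "control_singleton"))
    pri <- matrix(1, length(units), 1)
    em <- runEm(units, g, pri, 1)
    expect_equal(em$model$p, 0.2, tolerance = 1e-6)
    expect_true(em$model$converged)
    expect_lte(em$model$nIterations, 50L)
    expect_true(all(diff(em$model$loglikTrace) > -1e-9))
})

test_that("complete parental data gives the parental allele frequency", {
    set.seed(21)
    cfg <- simConfig(counts = data.frame(cases = 0, controls = 0,
                                         triads = 40, multiplex = 0),
                     nMarkers = 3, fst = 0, seed = 21)
    st <- simulateStudy(cfg)
    u <- familyUnits(st)
    g <- genotypes(st)[1, ]
    parents <- unlist(lapply(u, function(x) c(x@father, x@mother)))
    em <- runEm(u, g, matrix(1, length(u), 1), 1)
    expect_equal(em$model$p, mean(g[parents]) / 2, tolerance = 1e-5)
    # degenerate posteriors: every family sits on its observed mating type
    expect_equal(unname(em$posteriors$origin[, 1]), rep(1, length(u)))
})

test_that("z is frozen at the null without two-affected-sib units", {
    g <- c(2L, 1L, 0L, 1L)
    units <- lapply(1:4, function(i)
        FamilyUnit(sprintf("U%d", i), affectedSibs = i,
                   designTag = "case_singleton"))
    em <- runEm(units, g, matrix(1, 4, 1), 1)
    expect_equal(em$model$z, c(0.25, 0.5, 0.25))
})

test_that("monomorphic marker hits the clamp in at most two iterations", {
    g <- rep(2L, 8)
    units <- lapply(1:8, function(i)
        FamilyUnit(sprintf("U%d", i), affectedSibs = i,
                   designTag = "case_singleton"))
    em <- runEm(units, g, matrix(1, 8, 1), 1)
    expect_equal(em$model$p, 1 - 1e-6)
    expect_lte(em$model$nIterations, 2L)
})

test_that("permuting subpopulation labels permutes the estimates", {
    cfg <- scenarioTwoConfig(nMarkers = 40, fst = 0.2, scale = 10 / 750,
                             seed = 9)
    st <- simulateStudy(cfg)
    u <- familyUnits(st)
    g <- genotypes(st)[3, ]
    lab <- S4Vectors::metadata(st)$truth$subpop
    pri <- familyOriginPriors(lab, u, 2)
    em1 <- runEm(u, g, pri, 2, labels = lab)
    em2 <- runEm(u, g, pri[, 2:1], 2, labels = 3L - lab)
    expect_equal(em1$model$p, rev(em2$model$p), tolerance = 1e-9)
    expect_equal(em1$model$z, em2$model$z, tolerance = 1e-9)
})
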