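test_that("simulation is deterministic under the seed", {
    cfg <- simConfig(nLoci = 60, nGroups = 3, accessionsPerGroup = 8,
                     seed = 9)
    a <- simulateCalled(cfg)
    b <- simulateCalled(cfg)
    expect_identical(dosage(a$truth$genotypes), dosage(b$truth$genotypes))
    expect_identical(depthA(a$adm), depthA(b$adm))
    expect_identical(dosage(a$gm), dosage(b$gm))
    ta <- simulateBinaryTrait(a$truth)
    tb <- simulateBinaryTrait(b$truth)
    expect_identical(ta, tb)
    ca <- simulateDualCatalogs(a$truth, 0.5)
    cb <- simulateDualCatalogs(b$truth, 0.5)
    expect_identical(as.character(tagSequences(ca$uneak)),
                     as.character(tagSequences(cb$uneak)))
})

test_that("divergence limits behave as expected", {
    flat <- simulatePopulation(simConfig(nLoci = 50, nGroups = 4,
                                         accessionsPerGroup = 5,
                                         divergence = 0, seed = 2))
    expect_true(all(flat$groupFreqB == flat$groupFreqB[, 1]))

    # strong divergence separates group frequencies beyond sampling noise
    deltas <- vapply(1:20, function(s) {
        tr <- simulatePopulation(simConfig(nLoci = 100, nGroups = 2,
                                           accessionsPerGroup = 30,
                                           divergence = 0.3, seed = s))
        mean(abs(tr$groupFreqB[, 1] - tr$groupFreqB[, 2]))
    }, 0)
    nulls <- vapply(1:20, function(s) {
        tr <- simulatePopulation(simConfig(nLoci = 100, nGroups = 2,
                                           accessionsPerGroup = 30,
                                           divergence = 0, seed = 100 + s))
        d <- dosage(tr$genotypes)
        g1 <- colnames(d)[tr$groups$group == "G1"]
        g2 <- colnames(d)[tr$groups$group == "G2"]
        mean(abs(rowMeans(d[, g1]) - rowMeans(d[, g2])) / 2)
    }, 0)
    expect_gt(mean(deltas), max(nulls))
})

test_that("residual heterozygosity and inbreeding are honored", {
    none <- simulatePopulation(simConfig(nLoci = 80, nGroups = 2,
                                         accessionsPerGroup = 20,
                                         residualHet = 0, seed = 3))
    expect_identical(sum(dosage(none$genotypes) == 1L), 0L)

    some <- simulatePopulation(simConfig(nLoci = 400, nGroups = 2,
                                         accessionsPerGroup = 100,
                                         residualHet = 0.01, seed = 4))
    hetObs <- mean(dosage(some$genotypes) == 1L)
    expect_lt(abs(hetObs - 0.01), 0.004)
})

test_that("read-depth generation honors its generative model", {
    tr <- simulatePopulation(simConfig(nLoci = 30, nGroups = 2,
                                       accessionsPerGroup = 5, seed = 5))
    cfgAllMiss <- tr$cfg
    cfgAllMiss$missingTagRate <- 1
    allMiss <- simulateReadDepths(tr, cfgAllMiss)
    expect_true(all(totalDepth(allMiss) == 0L))

    clean <- simulatePopulation(simConfig(nLoci = 30, nGroups = 2,
                                          accessionsPerGroup = 5,
                                          residualHet = 0, errorRate = 0,
                                          seed = 5))
    adm <- simulateReadDepths(clean)
    hom <- dosage(clean$genotypes)
    expect_true(all(depthB(adm)[hom == 0L] == 0L))
    expect_true(all(depthA(adm)[hom == 2L] == 0L))

    # law of large numbers on >= 1e5 cells: the pre-dropout depth mean
    big <- simulatePopulation(simConfig(nLoci = 250, seed = 6))
    admB <- simulateReadDepths(big)
    ncell <- length(totalDepth(admB))
    expect_gte(ncell, 1e5)
    realized <- sum(totalDepth(admB)) /
        ((1 - big$cfg$missingTagRate) * ncell)
    expect_lt(abs(realized - big$cfg$meanDepth) / big$cfg$meanDepth, 0.05)
})

test_that("dual-catalog overlap fraction controls the truth pairing", {
    tr <- simulatePopulation(simConfig(nLoci = 60, nGroups = 2,
                                       accessionsPerGroup = 5, seed = 7))
    none <- simulateDualCatalogs(tr, overlapFraction = 0)
    expect_identical(nrow(none$pairs), 0L)
    both <- simulateDualCatalogs(tr, overlapFraction = 1)
    expect_identical(nrow(both$pairs), 60L)
    expect_true(all(locusId(both$uneak) %in% both$pairs$uneak))
})

test_that("binary trait follows the penetrance table", {
    tr <- simulatePopulation(simConfig(nLoci = 200, seed = 8))
    g <- minorDosage(tr$genotypes)[tr$causalLocus, ]

    rec <- simulateBinaryTrait(tr, penetrance = c(1, 1, 0))
    expect_identical(rec$phenotype, unname(as.integer(g < 2L)))

    flat <- simulateBinaryTrait(tr, penetrance = c(0.5, 0.5, 0.5))
    n <- length(flat$phenotype)
    expect_lt(abs(mean(flat$phenotype) - 0.5), 4 * sqrt(0.25 / n))

    dom <- simulateBinaryTrait(tr, penetrance = c(0, 1, 1))
    expRate <- mean(g >= 1L)
    expect_lt(abs(mean(dom$phenotype) - expRate),
              4 * sqrt(expRate * (1 - expRate) / n) + 1e-9)

    withNA <- simulateBinaryTrait(tr, naRate = 0.3)
    expect_gt(sum(is.na(withNA$phenotype)), 0L)
    expect_error(simulateBinaryTrait(tr, causalLocus = "nope"), "unknown")
})

test_that("the caller recovers truth genotypes at high depth", {
    cfg <- simConfig(nLoci = 250, nGroups = 2, accessionsPerGroup = 100,
                     meanDepth = 30, errorRate = 0.005, seed = 10)
    sim <- simulateCalled(cfg)
    td <- dosage(sim$truth$genotypes)
    cd <- dosage(sim$gm)
    ok <- !is.na(cd)
    expect_gte(mean(td[ok] == cd[ok]), 0.99)
})

test_that("masking genotypes at random refreshes the statistics", {
    gm <- simulatePopulation(simConfig(nLoci = 100, nGroups = 2,
                                       accessionsPerGroup = 25,
                                       seed = 11))$genotypes
    masked <- injectMissing(gm, 0.2, seed = 1)
    pm <- mean(is.na(dosage(masked)))
    expect_lt(abs(pm - 0.2), 0.02)
    expect_equal(unname(callRate(masked)),
                 unname(rowSums(!is.na(dosage(masked))) / ncol(masked)))
    expect_identical(dosage(injectMissing(gm, 0.2, seed = 1)),
                     dosage(masked))
})
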