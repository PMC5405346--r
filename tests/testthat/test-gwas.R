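test_that("kinship has VanRaden structure", {
    gm <- randomGm(150, 25, missRate = 0.2, seed = 31)
    K <- vanRadenKinship(gm)
    expect_true(isSymmetric(K))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)

    # accessions with identical genotypes are indistinguishable in K
    d <- dosage(gm)
    d <- cbind(d, twin = d[, 1])
    colnames(d)[1] <- "orig"
    K2 <- vanRadenKinship(GenotypeCalls(d))
    expect_equal(K2["orig", "twin"], K2["orig", "orig"])
    expect_equal(unname(K2["twin", ]), unname(K2["orig", ]))

    mono <- makeGm(matrix(0L, 5, 4))
    expect_error(vanRadenKinship(mono), "polymorphic")
})

test_that("kinship diagonal reflects inbreeding in a selfed panel", {
    tr <- simulatePopulation(simConfig(nLoci = 800, nGroups = 1,
                                       accessionsPerGroup = 120,
                                       divergence = 0,
                                       residualHet = 0.005, seed = 32))
    K <- vanRadenKinship(tr$genotypes)
    # near-fully inbred: mean diagonal close to 1 + F with F ~ 1
    expect_gt(mean(diag(K)), 1.7)
    expect_lt(mean(diag(K)), 2.3)
})

test_that("Bonferroni threshold is alpha over the test count", {
    expect_equal(bonferroniThreshold(0.05, 1), 0.05)
    expect_equal(bonferroniThreshold(0.05, 10), 0.005)
    expect_error(bonferroniThreshold(0.05, 0), "at least 1")
})

test_that("the scan reduces to ordinary least squares without kinship", {
    sim <- simulateCalled(simConfig(nLoci = 60, nGroups = 2,
                                    accessionsPerGroup = 40, seed = 33))
    gm <- filterMarkers(sim$gm)$genotypes
    ph <- simulateBinaryTrait(sim$truth)
    y <- setNames(ph$phenotype, ph$accession)
    sc <- mlmScan(y, gm, K = NULL)
    G <- minorDosage(gm)
    for (i in seq_len(nrow(gm))) {
        x <- G[i, names(y)]
        if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
        if (length(unique(x)) < 2) {
            expect_true(is.na(sc$p[i]))
            next
        }
        ref <- summary(lm(y ~ x))$coefficients["x", ]
        expect_equal(sc$effect[i], unname(ref["Estimate"]), tolerance = 1e-10)
        expect_equal(sc$p[i], unname(ref["Pr(>|t|)"]), tolerance = 1e-8)
    }
})

test_that("p-values are invariant to a joint permutation of accessions", {
    sim <- simulateCalled(simConfig(nLoci = 50, nGroups = 2,
                                    accessionsPerGroup = 30, seed = 34))
    gm <- filterMarkers(sim$gm)$genotypes
    K <- vanRadenKinship(gm)
    ph <- simulateBinaryTrait(sim$truth)
    y <- setNames(ph$phenotype, ph$accession)
    pcs <- ppcaGenotypes(gm, nComponents = 2, seed = 1)$scores
    sc1 <- mlmScan(y, gm, K, pcs, nPcs = 1)
    perm <- sample(names(y))
    sc2 <- mlmScan(y[perm], gm[, perm], K[perm, perm], pcs[perm, ],
                   nPcs = 1)
    expect_equal(sc1$p, sc2$p, tolerance = 1e-9)
    expect_equal(attr(sc1, "lambda"), attr(sc2, "lambda"),
                 tolerance = 1e-6)
})

test_that("null p-values are near-uniform and family-wise error is held", {
    sim <- simulateCalled(simConfig(nLoci = 2000, nGroups = 3,
                                    accessionsPerGroup = 50, seed = 35))
    gm <- filterMarkers(sim$gm,
                        filterThresholds(minMaf = 0.05))$genotypes
    K <- vanRadenKinship(gm)
    set.seed(77)
    y <- setNames(rnorm(ncol(gm)), colnames(gm))
    sc <- mlmScan(y, gm, K)
    p <- sc$p[!is.na(sc$p)]
    expect_gt(length(p), 1000)
    ks <- suppressWarnings(ks.test(p, "punif"))
    expect_lt(unname(ks$statistic), 0.05)

    hits <- vapply(1:20, function(r) {
        set.seed(1000 + r)
        yr <- setNames(rnorm(ncol(gm)), colnames(gm))
        any(mlmScan(yr, gm[1:400, ], K)$significant, na.rm = TRUE)
    }, TRUE)
    expect_lte(sum(hits), 1L)
})

test_that("BIC selects structure PCs when and only when they matter", {
    tr <- simulatePopulation(simConfig(nLoci = 400, nGroups = 2,
                                       accessionsPerGroup = 60,
                                       divergence = 0.3, seed = 36))
    gm <- tr$genotypes
    K <- vanRadenKinship(gm)
    pcs <- ppcaGenotypes(gm, nComponents = 4, seed = 1)$scores
    expect_identical(selectPcsBIC(
        setNames(rnorm(ncol(gm)), colnames(gm)), pcs, K, maxPcs = 0), 0L)

    set.seed(5)
    yStruct <- setNames(scale(pcs[, 1])[, 1] * 2 + rnorm(ncol(gm), 0, 0.5),
                        colnames(gm))
    expect_gte(selectPcsBIC(yStruct, pcs, K = NULL, maxPcs = 3), 1L)

    noiseWins <- vapply(1:50, function(r) {
        set.seed(2000 + r)
        yr <- setNames(rnorm(ncol(gm)), colnames(gm))
        selectPcsBIC(yr, pcs, K = NULL, maxPcs = 3) == 0L
    }, TRUE)
    expect_gt(mean(noiseWins), 0.5)
})

test_that("a fully penetrant recessive locus tops the scan", {
    sim <- simulateCalled(simConfig(nLoci = 300, nGroups = 2,
                                    accessionsPerGroup = 100, seed = 37))
    gm <- filterMarkers(sim$gm)$genotypes
    K <- vanRadenKinship(gm)
    ph <- simulateBinaryTrait(sim$truth, penetrance = c(0, 0, 1))
    y <- setNames(ph$phenotype, ph$accession)
    sc <- mlmScan(y, gm, K)
    expect_identical(sc$locus[which.min(sc$p)], sim$truth$causalLocus)
    expect_true(sc$significant[sc$locus == sim$truth$causalLocus])
})

test_that("per-marker REML agrees with P3D on a well-behaved panel", {
    sim <- simulateCalled(simConfig(nLoci = 40, nGroups = 2,
                                    accessionsPerGroup = 30, seed = 38))
    gm <- filterMarkers(sim$gm)$genotypes
    K <- vanRadenKinship(gm)
    ph <- simulateBinaryTrait(sim$truth)
    y <- setNames(ph$phenotype, ph$accession)
    p3d <- mlmScan(y, gm, K, method = "p3d")
    exact <- mlmScan(y, gm, K, method = "exact")
    keep <- !is.na(p3d$p)
    expect_gt(cor(-log10(p3d$p[keep]), -log10(exact$p[keep])), 0.95)
    expect_identical(p3d$locus[which.min(p3d$p)],
                     exact$locus[which.min(exact$p)])
})
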