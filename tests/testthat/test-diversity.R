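test_that("accession scores are one minus the missing fraction", {
    d <- cbind(full = c(0L, 1L, 2L, 0L, 1L),
               part = c(0L, NA, 2L, NA, 1L),
               gone = rep(NA_integer_, 5))
    gm <- makeGm(d)
    sc <- accessionScore(gm)
    expect_equal(unname(sc), c(1, 0.6, 0))
    expect_error(accessionScore(gm, "nobody"), "unknown accession")
})

test_that("downsampling stops inside the score band", {
    d <- matrix(0L, 10, 3)
    d[5:10, 2] <- NA   # 60% missing -> score 0.4
    d[4:10, 3] <- NA   # 70% missing -> score 0.3
    gm <- makeGm(d)
    sc <- accessionScore(gm)
    expect_equal(unname(sc), c(1, 0.4, 0.3))

    # acceptance band property over many draws
    set.seed(1)
    for (i in 1:200) {
        sub <- downsampleGroup(gm, colnames(gm), threshold = 1.2,
                               tolerance = 0.5)
        s <- sum(accessionScore(gm, sub))
        expect_gte(s, 0.7); expect_lte(s, 1.7)
    }
    # single-accession subsets arise when one score reaches the band
    expect_identical(downsampleGroup(gm, "S01", 1.2, 0.5, seed = 1), "S01")
    expect_error(downsampleGroup(gm, c("S02", "S03"), 5, 0.5),
                 "cannot reach")
})

test_that("accepted-subset distribution matches exhaustive enumeration", {
    # three accessions with scores 0.9, 0.7, 0.5; threshold 1.2 +/- 0.5
    scores <- c(a = 0.9, b = 0.7, c = 0.5)
    d <- matrix(0L, 10, 3, dimnames = list(NULL, names(scores)))
    d[10, 1] <- NA
    d[8:10, 2] <- NA
    d[6:10, 3] <- NA
    gm <- makeGm(d)
    expect_equal(unname(accessionScore(gm)), unname(scores))

    # oracle: walk all 6 orderings of the acceptance procedure
    perms <- list(c("a","b","c"), c("a","c","b"), c("b","a","c"),
                  c("b","c","a"), c("c","a","b"), c("c","b","a"))
    outcomes <- vapply(perms, function(p) {
        cum <- cumsum(scores[p])
        k <- which(cum >= 1.2 - 0.5)[1]
        if (cum[k] <= 1.2 + 0.5)
            paste(sort(p[seq_len(k)]), collapse = "+") else NA_character_
    }, "")
    expected <- table(outcomes) / sum(!is.na(outcomes))

    set.seed(99)
    draws <- replicate(10000, paste(sort(downsampleGroup(
        gm, names(scores), 1.2, 0.5)), collapse = "+"))
    got <- table(draws) / length(draws)
    expect_setequal(names(got), names(expected))
    for (k in names(expected))
        expect_lt(abs(got[[k]] - expected[[k]]),
                  4 * sqrt(expected[[k]] * (1 - expected[[k]]) / 10000) +
                      0.005)
})

test_that("private-allele counts match the brute-force oracle", {
    gm <- randomGm(200, 20, missRate = 0.3, seed = 12)
    grp <- colnames(gm)[1:7]
    cmp <- colnames(gm)[8:20]
    expect_identical(uniqueAlleles(gm, grp, cmp),
                     bruteUniqueAlleles(gm, grp, cmp))
    # group contained in comparison -> nothing private
    expect_identical(uniqueAlleles(gm, grp, colnames(gm)), 0L)
    expect_error(uniqueAlleles(gm, character(0), cmp), "empty group")
    # partition: private + shared = alleles observed in the group
    pres <- GBSpanel:::.allelePresence(dosage(gm))
    inG <- GBSpanel:::.observedAlleles(pres, grp)
    inC <- GBSpanel:::.observedAlleles(pres, cmp)
    expect_identical(uniqueAlleles(gm, grp, cmp) + sum(inG & inC),
                     sum(inG))
})

test_that("a hom-minor group contributes exactly its private allele", {
    d <- rbind(c(2L, 2L, 0L, 0L, 0L))
    gm <- makeGm(d)
    expect_identical(uniqueAlleles(gm, c("S01", "S02"),
                                   c("S03", "S04", "S05")), 1L)
})

test_that("standardized counts reduce to plain counts without downsampling", {
    # complete data: every accession scores 1, so a threshold equal to
    # the group size with a sub-unit tolerance keeps whole groups
    gm <- randomGm(80, 12, missRate = 0, seed = 13)
    X <- colnames(gm)[1:6]; Y <- colnames(gm)[7:12]
    groups <- data.frame(accession = colnames(gm),
                         group = rep(c("X", "Y"), each = 6))
    res <- standardizedUniqueAlleles(
        gm, groups, comparisons = list(AllOthers = "others"),
        spec = downsampleSpec(nIterations = 1, tolerance = 0.5, seed = 1))
    expect_identical(res$meanUnique[res$group == "X"],
                     as.numeric(uniqueAlleles(gm, X, Y)))
    expect_identical(res$meanUnique[res$group == "Y"],
                     as.numeric(uniqueAlleles(gm, Y, X)))
})

test_that("identical groups share all alleles after downsampling", {
    half <- matrix(sample(0:2, 40 * 6, TRUE), 40, 6)
    gm <- makeGm(cbind(half, half))
    groups <- data.frame(accession = colnames(gm),
                         group = rep(c("X", "Y"), each = 6))
    res <- standardizedUniqueAlleles(
        gm, groups, spec = downsampleSpec(nIterations = 5, seed = 3))
    expect_true(all(res$meanUnique == 0))
})

test_that("a divergent group shows the most private alleles", {
    # three groups descend from a shared bottleneck; the fourth samples
    # the ancestral pool directly and so retains alleles the others lost
    buildPanel <- function(seed) {
        set.seed(seed)
        L <- 300
        p <- runif(L, 0.05, 0.95)
        bn <- function(base, F)
            pmin(pmax(rbeta(L, base * (1 - F) / F,
                            (1 - base) * (1 - F) / F), 0), 1)
        qDom <- bn(p, 0.35)
        freqs <- list(bn(qDom, 0.05), bn(qDom, 0.05), bn(qDom, 0.05),
                      bn(p, 0.1))
        m <- do.call(cbind, lapply(freqs, function(q)
            matrix(rbinom(L * 12, 2, q), L, 12)))
        colnames(m) <- sprintf("a%02d", seq_len(ncol(m)))
        list(gm = makeGm(m),
             groups = data.frame(accession = colnames(m),
                                 group = rep(paste0("G", 1:4), each = 12)))
    }
    wins <- vapply(1:20, function(s) {
        pan <- buildPanel(s)
        res <- standardizedUniqueAlleles(
            pan$gm, pan$groups,
            spec = downsampleSpec(nIterations = 5, seed = s))
        means <- res$meanUnique[match(paste0("G", 1:4), res$group)]
        which.max(means) == 4L
    }, TRUE)
    expect_gte(sum(wins), 19L)
})

test_that("probabilistic PCA equals SVD PCA on complete data", {
    gm <- randomGm(60, 25, missRate = 0, seed = 14)
    pp <- ppcaGenotypes(gm, nComponents = 5)
    X <- scale(t(minorDosage(gm)) * 1.0, scale = FALSE)
    sv <- svd(X)
    ref <- sv$u[, 1:5] %*% diag(sv$d[1:5])
    for (c in 1:5) {
        flip <- sign(sum(ref[, c] * pp$scores[, c]))
        expect_lt(max(abs(ref[, c] * flip - pp$scores[, c])), 1e-6)
    }
    expect_true(pp$converged)
})

test_that("rank-1 structure loads on the first component", {
    set.seed(15)
    u <- rbinom(30, 2, 0.5)
    d <- outer(rep(1, 40), u)  # every locus identical across accessions
    gm <- makeGm(d)
    pp <- ppcaGenotypes(gm, nComponents = 3)
    expect_gt(pp$varExplained[1], 0.999)
})

test_that("EM handles missing data: separation, monotone fit, determinism", {
    tr <- simulatePopulation(simConfig(nLoci = 300, nGroups = 3,
                                       accessionsPerGroup = 30,
                                       divergence = 0.25, seed = 5))
    gm <- injectMissing(tr$genotypes, 0.2, seed = 9)
    pp <- ppcaGenotypes(gm, nComponents = 5, seed = 1)
    expect_true(pp$converged)
    # observed-data reconstruction error is (numerically) non-increasing
    expect_true(all(diff(pp$trace) <= 1e-8 * pp$trace[-length(pp$trace)]))
    sil <- cluster::silhouette(as.integer(factor(tr$groups$group)),
                               dist(pp$scores[, 1:2]))
    expect_gt(mean(sil[, 3]), 0.5)
    pp2 <- ppcaGenotypes(gm, nComponents = 5, seed = 1)
    expect_identical(pp$scores, pp2$scores)
    expect_error(ppcaGenotypes(gm, nComponents = 400), "smaller")
})
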