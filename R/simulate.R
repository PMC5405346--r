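#' @importFrom stats rbeta rbinom rnbinom runif rnorm setNames optimize
#'   pt sd
NULL

# independent RNG stream per simulation stage, derived from one seed
.simSeed <- function(seed, stream)
    as.integer((abs(as.numeric(seed)) %% 1e8) * 16 + stream)

#' Configuration of a synthetic GBS collection
#'
#' The defaults emulate a mostly-inbred crop germplasm panel of ~431
#' accessions in five genetic groups genotyped at low coverage: mean
#' read depth 4 with a heavy right tail, residual heterozygosity 0.5%,
#' and tag dropout tuned so that roughly 47% of genotype calls per SNP
#' are missing after threshold-based calling.
#'
#' @param nGroups number of genetic groups.
#' @param accessionsPerGroup accessions per group (scalar or vector of
#'   length `nGroups`).
#' @param nLoci number of biallelic SNP loci.
#' @param divergence Balding–Nichols-style divergence parameter in
#'   `[0, 1)` controlling the spread of group allele frequencies around
#'   the ancestral frequency (0 = panmictic).
#' @param residualHet expected residual heterozygosity per locus
#'   (capped by the Hardy–Weinberg heterozygosity of the group).
#' @param meanDepth mean total read depth of covered cells.
#' @param depthDispersion negative-binomial size parameter of the depth
#'   distribution (smaller = heavier right tail).
#' @param missingTagRate probability that a (locus, accession) cell has
#'   no reads at all (tag dropout), in addition to sampling zeros of the
#'   depth distribution.
#' @param errorRate per-read probability that a read reports the wrong
#'   allele.
#' @param seed integer seed fixing all randomness; each simulation stage
#'   draws from its own stream derived from this seed.
#' @return a `SimConfig` list.
#' @export
simConfig <- function(nGroups = 5L,
                      accessionsPerGroup = c(87L, 86L, 86L, 86L, 86L),
                      nLoci = 3000L, divergence = 0.15,
                      residualHet = 0.005, meanDepth = 4,
                      depthDispersion = 0.8, missingTagRate = 0.30,
                      errorRate = 0.01, seed = 1L) {
    if (length(accessionsPerGroup) == 1L)
        accessionsPerGroup <- rep(accessionsPerGroup, nGroups)
    stopifnot(nGroups >= 1L, length(accessionsPerGroup) == nGroups,
              all(accessionsPerGroup >= 1L), nLoci >= 1L,
              divergence >= 0, divergence < 1,
              residualHet >= 0, residualHet <= 1,
              meanDepth > 0, depthDispersion > 0,
              missingTagRate >= 0, missingTagRate <= 1,
              errorRate >= 0, errorRate <= 1)
    structure(list(nGroups = as.integer(nGroups),
                   accessionsPerGroup = as.integer(accessionsPerGroup),
                   nLoci = as.integer(nLoci), divergence = divergence,
                   residualHet = residualHet, meanDepth = meanDepth,
                   depthDispersion = depthDispersion,
                   missingTagRate = missingTagRate,
                   errorRate = errorRate, seed = as.integer(seed)),
              class = "SimConfig")
}

#' Simulate a structured, mostly-inbred collection
#'
#' Per locus an ancestral allele frequency is drawn uniformly on
#' (0.05, 0.95); group frequencies are drawn around it from a
#' Balding–Nichols Beta distribution with divergence parameter `F`
#' (shape `p(1-F)/F`, `(1-p)(1-F)/F`).  Genotypes are drawn with an
#' inbreeding level chosen so the expected heterozygosity equals
#' `residualHet` (each cell is autozygous with probability
#' `1 - residualHet / (2 q (1 - q))`, clipped to `[0, 1]`).
#'
#' @param cfg a [simConfig()].
#' @return a `SimTruth` list with elements `genotypes` (a
#'   [GenotypeCalls-class] of true genotypes, no missing data), `groups`
#'   (group table), `groupFreqB` (loci x groups allele-B frequencies),
#'   `ancestralFreqB`, `causalLocus` (the locus whose realized minor
#'   allele frequency is closest to 0.3, a convenient major-gene
#'   candidate for trait simulation) and `cfg`.
#' @export
simulatePopulation <- function(cfg = simConfig()) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(.simSeed(cfg$seed, 1L))
    L <- cfg$nLoci
    G <- cfg$nGroups
    N <- sum(cfg$accessionsPerGroup)
    p <- runif(L, 0.05, 0.95)
    F <- cfg$divergence
    if (F == 0) {
        Q <- matrix(p, L, G)
    } else {
        Q <- matrix(rbeta(L * G, rep(p, G) * (1 - F) / F,
                          rep(1 - p, G) * (1 - F) / F), L, G)
    }
    dimnames(Q) <- list(sprintf("L%04d", seq_len(L)),
                        sprintf("G%d", seq_len(G)))
    grp <- rep(colnames(Q), cfg$accessionsPerGroup)
    accs <- sprintf("ACC%03d", seq_len(N))
    Qcell <- Q[, match(grp, colnames(Q)), drop = FALSE]
    hw <- 2 * Qcell * (1 - Qcell)
    fAuto <- ifelse(hw > 0, pmin(1, pmax(0, 1 - cfg$residualHet / hw)), 1)
    n <- L * N
    auto <- runif(n) < fAuto
    dosB <- ifelse(auto, 2L * rbinom(n, 1L, Qcell), rbinom(n, 2L, Qcell))
    dosB <- matrix(as.integer(dosB), L, N,
                   dimnames = list(rownames(Q), accs))
    gm <- GenotypeCalls(dosB)
    groups <- asGroupTable(data.frame(accession = accs, group = grp))
    m <- maf(gm)
    causal <- names(which.min(abs(m - 0.3)))
    structure(list(genotypes = gm, groups = groups, groupFreqB = Q,
                   ancestralFreqB = setNames(p, rownames(Q)),
                   causalLocus = causal, cfg = cfg),
              class = "SimTruth")
}

#' Simulate per-allele read depths from true genotypes
#'
#' Each cell is empty (tag dropout) with probability `missingTagRate`;
#' otherwise its total depth is negative-binomial with mean `meanDepth`
#' and size `depthDispersion`.  Reads are split between the two alleles:
#' homozygotes send each read to the wrong allele with probability
#' `errorRate`, heterozygotes sample alleles fairly.
#'
#' @param truth a `SimTruth` from [simulatePopulation()].
#' @param cfg the [simConfig()] (defaults to `truth$cfg`).
#' @return an [AlleleDepthMatrix-class].
#' @export
simulateReadDepths <- function(truth, cfg = truth$cfg) {
    stopifnot(inherits(truth, "SimTruth"))
    set.seed(.simSeed(cfg$seed, 2L))
    dosB <- dosage(truth$genotypes)
    n <- length(dosB)
    depth <- rnbinom(n, size = cfg$depthDispersion, mu = cfg$meanDepth)
    depth[runif(n) < cfg$missingTagRate] <- 0L
    pB <- c(cfg$errorRate, 0.5, 1 - cfg$errorRate)[dosB + 1L]
    b <- rbinom(n, depth, pB)
    a <- depth - b
    dims <- dimnames(dosB)
    AlleleDepthMatrix(matrix(as.integer(a), nrow(dosB),
                             dimnames = dims),
                      matrix(as.integer(b), nrow(dosB),
                             dimnames = dims))
}

.randomTag <- function(n, len) {
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), "")
}

#' Simulate two partially overlapping SNP catalogs
#'
#' Every locus of the truth set receives a random 64-bp tag in the UNEAK
#' dialect or an 80-bp tag in the Stacks dialect.  A fraction
#' `overlapFraction` of loci appears in both catalogs: the Stacks copy
#' embeds the 64-bp tag as a substring, optionally with up to
#' `mismatches` base substitutions injected outside the SNP position.
#' The remaining loci are private to one catalog (split evenly at
#' random).  The ground-truth pairing is returned for audit.
#'
#' @param truth a `SimTruth`.
#' @param overlapFraction fraction of loci present in both catalogs.
#' @param cfg the [simConfig()] (defaults to `truth$cfg`).
#' @param mismatches number of base substitutions injected into each
#'   embedded 64-mer (0–3).
#' @return list with `uneak` and `stacks` [TagCatalog-class] objects and
#'   `pairs`, a data.frame of true (uneak, stacks) locus-id pairs.
#' @export
simulateDualCatalogs <- function(truth, overlapFraction = 0.8,
                                 cfg = truth$cfg, mismatches = 0L) {
    stopifnot(inherits(truth, "SimTruth"),
              overlapFraction >= 0, overlapFraction <= 1,
              mismatches >= 0L, mismatches <= 3L)
    set.seed(.simSeed(cfg$seed, 3L))
    loci <- rownames(truth$genotypes)
    L <- length(loci)
    bases <- c("A", "C", "G", "T")
    aA <- sample(bases, L, replace = TRUE)
    aB <- vapply(aA, function(x) sample(setdiff(bases, x), 1L), "")
    tag64 <- .randomTag(L, 64L)
    off64 <- sample(0:63, L, replace = TRUE)
    substr(tag64, off64 + 1L, off64 + 1L) <- aA
    nShared <- round(overlapFraction * L)
    shared <- sort(sample(L, nShared))
    rest <- setdiff(seq_len(L), shared)
    toStacks <- rest[runif(length(rest)) < 0.5]
    uneakIdx <- sort(c(shared, setdiff(rest, toStacks)))

    stacksIdx <- sort(c(shared, toStacks))
    start80 <- sample(0:16, L, replace = TRUE)  # 0-based embed position
    tag80 <- character(L)
    for (i in stacksIdx) {
        flank <- .randomTag(1L, 16L)
        t64 <- tag64[i]
        if (mismatches > 0L && i %in% shared) {
            pos <- setdiff(seq_len(64L), off64[i] + 1L)
            hit <- sample(pos, mismatches)
            for (h in hit) {
                old <- substr(t64, h, h)
                substr(t64, h, h) <- sample(setdiff(bases, old), 1L)
            }
        }
        if (!(i %in% shared)) t64 <- .randomTag(1L, 64L)
        s <- start80[i]
        tag80[i] <- paste0(substr(flank, 1L, s), t64,
                           substr(flank, s + 1L, 16L))
        if (!(i %in% shared))
            substr(tag80[i], s + off64[i] + 1L, s + off64[i] + 1L) <- aA[i]
    }
    uneak <- TagCatalog(loci[uneakIdx], tag64[uneakIdx], off64[uneakIdx],
                        aA[uneakIdx], aB[uneakIdx], source = "UNEAK")
    stacksIds <- sub("^L", "ST", loci)
    stacks <- TagCatalog(stacksIds[stacksIdx], tag80[stacksIdx],
                         (start80 + off64)[stacksIdx],
                         aA[stacksIdx], aB[stacksIdx], source = "STACKS")
    pairs <- data.frame(uneak = loci[shared], stacks = stacksIds[shared])
    list(uneak = uneak, stacks = stacks, pairs = pairs)
}

#' Simulate a binary trait controlled by one major locus
#'
#' Each accession's phenotype is Bernoulli with success probability
#' given by the penetrance of its genotype at the causal locus.
#'
#' @param truth a `SimTruth`.
#' @param causalLocus locus identifier (default: `truth$causalLocus`).
#' @param penetrance numeric length-3 vector: `P(trait = 1)` for
#'   genotypes (HOM_MAJOR, HET, HOM_MINOR).  The default is a fully
#'   penetrant trait recessive for the minor allele.
#' @param naRate fraction of phenotypes recorded as `NA` at random.
#' @param seed integer seed (defaults to the config's trait stream).
#' @return data.frame with columns `accession` and `phenotype`
#'   (0, 1 or NA).
#' @export
simulateBinaryTrait <- function(truth, causalLocus = truth$causalLocus,
                                penetrance = c(0, 0, 1), naRate = 0,
                                seed = .simSeed(truth$cfg$seed, 4L)) {
    stopifnot(inherits(truth, "SimTruth"), length(penetrance) == 3L,
              all(penetrance >= 0 & penetrance <= 1))
    if (!causalLocus %in% rownames(truth$genotypes))
        stop("unknown causal locus: ", causalLocus)
    set.seed(seed)
    g <- minorDosage(truth$genotypes)[causalLocus, ]
    y <- rbinom(length(g), 1L, penetrance[g + 1L])
    if (naRate > 0)
        y[runif(length(y)) < naRate] <- NA_integer_
    data.frame(accession = colnames(truth$genotypes), phenotype = y)
}

#' Mask genotype calls as missing at random
#'
#' Sets a fraction of cells of a genotype matrix to missing, uniformly
#' at random, and refreshes the per-locus statistics.  Useful for
#' emulating incomplete panels from complete truth genotypes.
#'
#' @param gm a [GenotypeCalls-class].
#' @param rate fraction of cells to mask.
#' @param seed integer seed.
#' @return the masked [GenotypeCalls-class].
#' @export
injectMissing <- function(gm, rate, seed = 1L) {
    stopifnot(rate >= 0, rate <= 1)
    set.seed(seed)
    d <- dosage(gm)
    d[runif(length(d)) < rate] <- NA_integer_
    rd <- rowData(gm)
    GenotypeCalls(d, alleleA = rd$alleleA, alleleB = rd$alleleB,
                  meanDepth = rd$meanDepth)
}
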