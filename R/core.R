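#' Allele coverage of an accession subset
#'
#' The fraction of alleles observed anywhere in the full genotype set
#' (two per biallelic SNP, counted as in [uniqueAlleles()]) that are
#' also observed within the subset.
#'
#' @param gm a [GenotypeCalls-class].
#' @param subset accession identifiers (non-empty).
#' @return fraction in `[0, 1]`.
#' @export
alleleCoverage <- function(gm, subset) {
    if (!length(subset)) stop("empty subset")
    pres <- .allelePresence(dosage(gm))
    full <- .observedAlleles(pres, colnames(gm))
    inSub <- .observedAlleles(pres, subset)
    sum(inSub & full) / sum(full)
}

#' Greedy allele-coverage core selection
#'
#' Deterministic greedy set cover over the allele-presence matrix:
#' repeatedly add the eligible accession contributing the most alleles
#' not yet covered (ties broken by higher call rate, then by
#' lexicographic accession id) until coverage reaches the target, then
#' make one backward pass dropping any accession whose removal keeps
#' coverage at or above the target.
#'
#' @param gm a [GenotypeCalls-class].
#' @param targetCoverage fraction of the full set's observed alleles
#'   the core must retain.
#' @param eligible accession identifiers available for selection
#'   (default: all).
#' @param maxSize optional cap on the core size; selection stops at the
#'   cap even if the target is not met.
#' @return a `CoreSet` list: `accessions`, `coverage`, `mafRetention`
#'   (fraction of SNPs whose minor allele frequency within the core is
#'   at least 0.01), `targetCoverage` and `metTarget`.
#' @export
greedyCore <- function(gm, targetCoverage = 0.95,
                       eligible = colnames(gm), maxSize = Inf) {
    stopifnot(targetCoverage >= 0, targetCoverage <= 1)
    eligible <- sort(unique(eligible))
    bad <- setdiff(eligible, colnames(gm))
    if (length(bad)) stop("unknown accession: ", bad[1L])
    pres <- .allelePresence(dosage(gm))
    P <- rbind(pres$A, pres$B)                # alleles x accessions
    full <- rowSums(P) > 0
    P <- P[full, , drop = FALSE]
    nAll <- nrow(P)
    cr <- colSums(!is.na(dosage(gm)))
    covered <- rep(FALSE, nAll)
    chosen <- character(0)
    pool <- eligible
    need <- ceiling(targetCoverage * nAll - 1e-9)
    while (sum(covered) < need && length(pool) &&
           length(chosen) < maxSize) {
        gain <- colSums(P[!covered, pool, drop = FALSE])
        best <- max(gain)
        if (best == 0) break
        cand <- pool[gain == best]
        cand <- cand[order(-cr[cand], cand)][1L]
        chosen <- c(chosen, cand)
        covered <- covered | P[, cand]
        pool <- setdiff(pool, cand)
    }
    if (!length(chosen) && length(pool)) {
        # degenerate targets still yield a usable (single-accession) core
        gain <- colSums(P[, pool, drop = FALSE])
        cand <- pool[gain == max(gain)]
        chosen <- cand[order(-cr[cand], cand)][1L]
        covered <- covered | P[, chosen]
    }
    if (sum(covered) < need && !is.finite(maxSize))
        stop("coverage target ", targetCoverage,
             " not reachable with eligible accessions; maximum ",
             "achievable coverage is ", round(sum(covered) / nAll, 4))
    # backward pass: drop redundant members (in selection order)
    for (acc in chosen) {
        rest <- setdiff(chosen, acc)
        if (length(rest) &&
            sum(rowSums(P[, rest, drop = FALSE]) > 0) >= need)
            chosen <- rest
    }
    cov <- sum(rowSums(P[, chosen, drop = FALSE]) > 0) / nAll
    coreM <- recomputeLocusStats(gm[, chosen])
    structure(list(accessions = chosen, coverage = cov,
                   mafRetention = mean(maf(coreM) >= 0.01, na.rm = TRUE),
                   targetCoverage = targetCoverage,
                   metTarget = cov >= targetCoverage - 1e-12),
              class = "CoreSet")
}

#' @export
print.CoreSet <- function(x, ...) {
    cat("CoreSet:", length(x$accessions), "accessions, coverage",
        sprintf("%.4f", x$coverage), "(target", x$targetCoverage,
        if (x$metTarget) "met)" else "NOT met)", "\n  maf >= 0.01 in",
        sprintf("%.1f%%", 100 * x$mafRetention), "of SNPs in the core\n")
    invisible(x)
}

#' Core selection with a sampling-intensity sweep
#'
#' Runs the greedy core selection at a descending sequence of sampling
#' intensities — each intensity `i` caps the core at
#' `ceiling(i * n_eligible)` accessions — and returns the smallest core
#' that meets the coverage target.  If no intensity meets the target,
#' the best-covering core is returned with `metTarget = FALSE`.
#'
#' @inheritParams greedyCore
#' @param intensities sampling intensities to try (descending).
#' @return a `CoreSet` (see [greedyCore()]) with an extra element
#'   `intensity`, the sampling intensity that produced it.
#' @export
intensitySweep <- function(gm, targetCoverage = 0.95,
                           eligible = colnames(gm),
                           intensities = seq(0.95, 0.05, by = -0.05)) {
    best <- NULL
    for (i in intensities) {
        cap <- ceiling(i * length(eligible))
        core <- greedyCore(gm, targetCoverage, eligible, maxSize = cap)
        core$intensity <- i
        if (core$metTarget &&
            (is.null(best) || !best$metTarget ||
             length(core$accessions) < length(best$accessions)))
            best <- core
        if (is.null(best) ||
            (!best$metTarget && core$coverage > best$coverage))
            best <- core
    }
    best
}
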