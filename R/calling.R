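#' Genotype-calling thresholds
#'
#' Fraction thresholds for calling genotypes from the two allele read
#' depths of a cell.  With `f` the fraction of reads carrying the cell's
#' less-sequenced ("alternate") allele, a cell is called homozygous when
#' `f < homMax`, missing when `homMax <= f < hetMin` (the ambiguous band),
#' and heterozygous when `f >= hetMin`.  Defaults are 5% and 10%.
#'
#' @param homMax upper (exclusive) alternate-read fraction for a
#'   homozygous call.
#' @param hetMin lower (inclusive) alternate-read fraction for a
#'   heterozygous call.
#' @return a `CallThresholds` list.
#' @export
callThresholds <- function(homMax = 0.05, hetMin = 0.10) {
    stopifnot(homMax > 0, homMax <= hetMin, hetMin < 1)
    structure(list(homMax = homMax, hetMin = hetMin),
              class = "CallThresholds")
}

#' Call one genotype from a pair of allele read depths
#'
#' The alternate allele is the less-sequenced allele of the cell, so the
#' alternate fraction never exceeds 0.5.  Cells with zero total depth are
#' missing before any fraction is computed.
#'
#' @param depthMajor,depthAlt read counts for the cell's more- and
#'   less-sequenced allele (order does not matter; the smaller count is
#'   treated as alternate).
#' @param thresholds a [callThresholds()] object.
#' @return `"HOM"`, `"HET"` or `"MISSING"`.
#' @examples
#' callGenotype(96, 4)   # "HOM"
#' callGenotype(93, 7)   # "MISSING" (ambiguous band)
#' callGenotype(85, 15)  # "HET"
#' @export
callGenotype <- function(depthMajor, depthAlt,
                         thresholds = callThresholds()) {
    if (depthMajor < 0 || depthAlt < 0)
        stop("read depths must be non-negative")
    total <- depthMajor + depthAlt
    if (total == 0) return("MISSING")
    f <- min(depthMajor, depthAlt) / total
    if (f < thresholds$homMax) "HOM"
    else if (f < thresholds$hetMin) "MISSING"
    else "HET"
}

#' Call a genotype matrix from allele read depths
#'
#' Applies the alternate-fraction rule of [callGenotype()] to every cell
#' of an [AlleleDepthMatrix-class].  Homozygous calls follow the allele
#' that carries the cell's reads; per-locus maf, call rate and
#' heterozygosity statistics are computed from the calls.
#'
#' @param adm an [AlleleDepthMatrix-class].
#' @param thresholds a [callThresholds()] object.
#' @param altMode how the "alternate" allele is defined: `"cell"`
#'   (default) takes the less-sequenced allele of each cell, so the
#'   alternate fraction never exceeds 0.5; `"locus"` fixes it per locus as
#'   the allele with the lower total read count across accessions and
#'   applies the fraction bands literally to that allele's fraction —
#'   under this reading cells homozygous for the locus-wise alternate
#'   allele land in the heterozygous band, which is why `"cell"` is the
#'   default.
#' @param alleleA,alleleB optional allele bases passed through to the
#'   result (defaults `"A"`/`"B"`).
#' @return a [GenotypeCalls-class] with rowData `meanDepth` filled in.
#' @export
callGenotypes <- function(adm, thresholds = callThresholds(),
                          altMode = c("cell", "locus"),
                          alleleA = "A", alleleB = "B") {
    altMode <- match.arg(altMode)
    a <- depthA(adm); b <- depthB(adm)
    tot <- a + b
    if (altMode == "cell") {
        alt <- pmin(a, b)
    } else {
        bMinor <- rowSums(b) <= rowSums(a)
        alt <- ifelse(bMinor[row(a)], b, a)
    }
    f <- ifelse(tot > 0, alt / tot, NA_real_)
    dos <- matrix(NA_integer_, nrow(a), ncol(a), dimnames = dimnames(a))
    hom <- !is.na(f) & f < thresholds$homMax
    het <- !is.na(f) & f >= thresholds$hetMin
    # homozygote direction: the allele carrying the cell's majority reads
    dos[hom] <- ifelse(b[hom] > a[hom], 2L, 0L)
    dos[het] <- 1L
    covered <- tot > 0
    meanDepth <- ifelse(rowSums(covered) > 0,
                        rowSums(tot) / rowSums(covered), NA_real_)
    GenotypeCalls(dos, alleleA = alleleA, alleleB = alleleB,
                  meanDepth = meanDepth)
}

#' Depth and missingness summary of a called SNP panel
#'
#' Summarizes a depth matrix and its genotype calls the way GBS panels
#' are usually reported: mean read depth over covered cells, percent
#' missing calls per SNP, and the number of SNPs meeting a minimum-depth
#' criterion.
#'
#' @param adm the [AlleleDepthMatrix-class] the calls were made from.
#' @param gm the [GenotypeCalls-class] derived from `adm`.
#' @param minDepth depth cutoffs `d` at which to count SNPs.
#' @param depthCriterion how a SNP qualifies at depth `d`: `"cell"`
#'   (default) requires every cell with a non-missing call to have total
#'   depth `>= d`; `"mean"` requires the SNP's mean depth over covered
#'   cells to be `>= d`.
#' @return a list with per-SNP vectors `meanDepth` and `percentMissing`,
#'   the panel-wide averages `avgDepth` and `avgPercentMissing`, and a
#'   data.frame `atDepth` with one row per cutoff giving the SNP count
#'   and the average depth/missingness of the qualifying SNPs.
#' @export
depthSummary <- function(adm, gm, minDepth = c(1L, 5L),
                         depthCriterion = c("cell", "mean")) {
    depthCriterion <- match.arg(depthCriterion)
    if (!identical(dim(adm), dim(gm)))
        stop("depth matrix and genotype calls have different shapes")
    tot <- totalDepth(adm)
    covered <- tot > 0
    meanDepth <- ifelse(rowSums(covered) > 0,
                        rowSums(tot) / rowSums(covered), NA_real_)
    d <- dosage(gm)
    pctMissing <- rowSums(is.na(d)) / ncol(d) * 100
    qualifies <- function(cut) {
        if (depthCriterion == "mean") !is.na(meanDepth) & meanDepth >= cut
        else apply(!is.na(d) & tot < cut, 1L, function(z) !any(z)) &
            rowSums(!is.na(d)) > 0
    }
    atDepth <- do.call(rbind, lapply(minDepth, function(cut) {
        q <- qualifies(cut)
        data.frame(minDepth = cut, nSNP = sum(q),
                   avgDepth = mean(meanDepth[q]),
                   avgPercentMissing = mean(pctMissing[q]))
    }))
    list(meanDepth = setNames(meanDepth, rownames(adm)),
         percentMissing = setNames(pctMissing, rownames(adm)),
         avgDepth = mean(meanDepth, na.rm = TRUE),
         avgPercentMissing = mean(pctMissing),
         atDepth = atDepth)
}
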