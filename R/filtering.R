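#' @importFrom Biostrings vcountPattern matchPattern neditStartingAt
NULL

#' Marker-filtering thresholds
#'
#' A SNP is retained when its minor allele frequency, call rate and
#' heterozygosity rate all pass.  Defaults reflect common practice for
#' mostly-inbred GBS panels: maf >= 0.01, call rate >= 0.2, and
#' heterozygosity <= 0.25 (values above that flag collapsed paralogs in
#' an inbred collection).
#'
#' @param minMaf minimum minor allele frequency.
#' @param minCallRate minimum fraction of accessions with a call.
#' @param maxHetRate maximum heterozygosity among non-missing calls.
#' @param minTaxaPerTag minimum number of accessions with reads for a
#'   tag (used by [tagTaxaFilter()]).
#' @return a `FilterThresholds` list.
#' @export
filterThresholds <- function(minMaf = 0.01, minCallRate = 0.2,
                             maxHetRate = 0.25, minTaxaPerTag = 5L) {
    stopifnot(minMaf >= 0, minMaf <= 1, minCallRate >= 0,
              minCallRate <= 1, maxHetRate >= 0, maxHetRate <= 1,
              minTaxaPerTag >= 0)
    structure(list(minMaf = minMaf, minCallRate = minCallRate,
                   maxHetRate = maxHetRate,
                   minTaxaPerTag = as.integer(minTaxaPerTag)),
              class = "FilterThresholds")
}

.markerPass <- function(gm, t) {
    rd <- rowData(gm)
    okCall <- rd$callRate >= t$minCallRate
    okMaf <- !is.na(rd$maf) & rd$maf >= t$minMaf
    okHet <- !is.na(rd$hetRate) & rd$hetRate <= t$maxHetRate
    list(pass = okCall & okMaf & okHet,
         failCall = !okCall,
         failMaf = okCall & !okMaf,
         failHet = okCall & okMaf & !okHet)
}

#' Filter SNP markers on maf, call rate and heterozygosity
#'
#' A marker is retained iff `maf >= minMaf`, `callRate >= minCallRate`
#' and `hetRate <= maxHetRate`.  Each excluded marker is attributed to
#' the first failing rule, in the fixed order (call rate, maf,
#' heterozygosity), so the report counts reconcile exactly with the
#' input and output dimensions.  The operation is idempotent.
#'
#' @param gm a [GenotypeCalls-class] with current locus statistics.
#' @param thresholds a [filterThresholds()] object.
#' @return list with `genotypes` (the retained subset) and `report`
#'   (input size, retained size, exclusion counts per rule).
#' @export
filterMarkers <- function(gm, thresholds = filterThresholds()) {
    p <- .markerPass(gm, thresholds)
    report <- structure(list(input = nrow(gm), retained = sum(p$pass),
                             excludedCallRate = sum(p$failCall),
                             excludedMaf = sum(p$failMaf),
                             excludedHetRate = sum(p$failHet)),
                        class = "FilterReport")
    list(genotypes = gm[p$pass, ], report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
    cat("Marker filter report:", x$input, "SNPs in,", x$retained,
        "retained\n  excluded: call rate", x$excludedCallRate,
        "| maf", x$excludedMaf, "| het rate", x$excludedHetRate, "\n")
    invisible(x)
}

#' Tag-level taxa filter
#'
#' Mirrors the discovery-pipeline practice of keeping only tags seen in
#' a minimum number of accessions: a locus passes when its tag has at
#' least `minTaxa` cells with non-zero read depth.
#'
#' @param adm an [AlleleDepthMatrix-class].
#' @param minTaxa minimum accessions with reads.
#' @return character vector of passing locus identifiers.
#' @export
tagTaxaFilter <- function(adm, minTaxa = 5L) {
    covered <- rowSums(totalDepth(adm) > 0)
    rownames(adm)[covered >= minTaxa]
}

#' Keep the first passing SNP per tag
#'
#' Multi-SNP tags (Stacks dialect) contribute at most one marker: per
#' tag sequence, SNPs are ordered by their offset and the first one that
#' passes [filterMarkers()] is kept; all other SNPs on that tag are
#' dropped.  Tags with no passing SNP contribute nothing.
#'
#' @param catalog a [TagCatalog-class]; records sharing a tag sequence
#'   are treated as SNPs on one tag.
#' @param gm a [GenotypeCalls-class] holding statistics for every
#'   catalog locus.
#' @param thresholds a [filterThresholds()] object.
#' @return the reduced [TagCatalog-class].
#' @export
firstSnpPerTag <- function(catalog, gm, thresholds = filterThresholds()) {
    idx <- match(locusId(catalog), rownames(gm))
    if (anyNA(idx))
        stop("catalog locus missing from genotype matrix: ",
             locusId(catalog)[is.na(idx)][1L])
    pass <- .markerPass(gm[idx, ], thresholds)$pass
    tagKey <- as.character(catalog@tagSeq)
    keep <- logical(length(catalog))
    for (grp in split(seq_along(keep), tagKey)) {
        grp <- grp[order(catalog@snpOffset[grp])]
        hit <- grp[pass[grp]]
        if (length(hit)) keep[hit[1L]] <- TRUE
    }
    catalog[sort(which(keep))]
}

#' Merge two SNP catalogs with genotype precedence
#'
#' Pairs loci discovered independently by the 64-bp (UNEAK) and 80-bp
#' (Stacks) pipelines and assembles the union data set.  Two loci are
#' paired when the 64-bp tag occurs within the 80-bp tag with identity
#' `>= minIdentity` over an overlap of at least `minOverlap` bases
#' (full-length embedding with up to `floor((1 - minIdentity) * 64)`
#' mismatches) *and* the two SNP offsets coincide under the alignment.
#' Paired loci appear once, with the genotypes called by the UNEAK
#' pipeline; unpaired loci from both catalogs pass through.  When one
#' tag matches several partners the best identity wins (ties go to the
#' lexicographically smallest partner id) and a warning is issued.
#'
#' @param uneak,stacks lists with elements `catalog` (a
#'   [TagCatalog-class]) and `genotypes` (a [GenotypeCalls-class]); the
#'   two genotype sets must cover identical accessions.
#' @param minIdentity minimum alignment identity for a pair.
#' @param minOverlap minimum aligned overlap in bases.
#' @return list with `catalog` (merged [TagCatalog-class]), `genotypes`
#'   (merged [GenotypeCalls-class]) and `pairs` (data.frame of uneak id,
#'   stacks id, mismatch count).
#' @export
unionCatalogs <- function(uneak, stacks, minIdentity = 0.95,
                          minOverlap = 60L) {
    uc <- uneak$catalog; ug <- uneak$genotypes
    sc <- stacks$catalog; sg <- stacks$genotypes
    if (!identical(sort(colnames(ug)), sort(colnames(sg))))
        stop("the two genotype sets must cover identical accessions")
    sg <- sg[, colnames(ug)]
    # align the shorter dialect's tags within the longer one's, so locus
    # membership of the union does not depend on argument order
    swap <- length(uc) && length(sc) &&
        stats::median(width(uc@tagSeq)) > stats::median(width(sc@tagSeq))
    pc <- if (swap) uc else sc   # subject (container) catalog
    qc <- if (swap) sc else uc   # query (embedded) catalog
    maxMM <- floor((1 - minIdentity) *
                   min(64L, if (length(qc)) min(width(qc@tagSeq)) else 64L))
    sSeqs <- pc@tagSeq
    cand <- vector("list", length(qc))
    for (i in seq_len(length(qc))) {
        pat <- qc@tagSeq[[i]]
        if (length(pat) < minOverlap) next
        hitSubj <- which(vcountPattern(pat, sSeqs,
                                       max.mismatch = maxMM) > 0)
        if (!length(hitSubj)) next
        rows <- lapply(hitSubj, function(j) {
            m <- matchPattern(pat, sSeqs[[j]], max.mismatch = maxMM)
            st <- BiocGenerics::start(m)
            mm <- neditStartingAt(pat, sSeqs[[j]], starting.at = st,
                                  with.indels = FALSE)
            # SNP offsets must coincide under the alignment
            ok <- (st - 1L + qc@snpOffset[i]) == pc@snpOffset[j]
            if (!any(ok)) return(NULL)
            data.frame(stacks = j, mismatches = min(mm[ok]))
        })
        rows <- do.call(rbind, rows)
        if (!is.null(rows) && nrow(rows)) cand[[i]] <- rows
    }
    # resolve to 1-1 pairing, best identity first
    pairs <- data.frame(uneak = integer(), stacks = integer(),
                        mismatches = integer())
    edges <- do.call(rbind, lapply(seq_along(cand), function(i)
        if (is.null(cand[[i]])) NULL else cbind(uneak = i, cand[[i]])))
    if (swap && !is.null(edges) && nrow(edges))
        edges <- data.frame(uneak = edges$stacks, stacks = edges$uneak,
                            mismatches = edges$mismatches)
    if (!is.null(edges) && nrow(edges)) {
        if (anyDuplicated(edges$uneak) || anyDuplicated(edges$stacks))
            warning("ambiguous tag pairing; keeping best identity")
        edges <- edges[order(edges$mismatches,
                             locusId(uc)[edges$uneak],
                             locusId(sc)[edges$stacks]), ]
        takenU <- logical(length(uc)); takenS <- logical(length(sc))
        for (k in seq_len(nrow(edges))) {
            i <- edges$uneak[k]; j <- edges$stacks[k]
            if (!takenU[i] && !takenS[j]) {
                takenU[i] <- TRUE; takenS[j] <- TRUE
                pairs <- rbind(pairs,
                               data.frame(uneak = i, stacks = j,
                                          mismatches = edges$mismatches[k]))
            }
        }
    }
    pairedStacks <- locusId(sc)[pairs$stacks]
    soloStacks <- setdiff(locusId(sc), pairedStacks)
    mergedCatalog <- TagCatalog(
        c(locusId(uc), soloStacks),
        c(as.character(uc@tagSeq),
          as.character(sc[soloStacks]@tagSeq)),
        c(uc@snpOffset, sc[soloStacks]@snpOffset),
        c(uc@alleleA, sc[soloStacks]@alleleA),
        c(uc@alleleB, sc[soloStacks]@alleleB),
        c(uc@source, sc[soloStacks]@source))
    dU <- dosage(ug)
    dS <- dosage(sg)[soloStacks, , drop = FALSE]
    merged <- GenotypeCalls(
        rbind(dU, dS),
        alleleA = c(rowData(ug)$alleleA, rowData(sg[soloStacks, ])$alleleA),
        alleleB = c(rowData(ug)$alleleB, rowData(sg[soloStacks, ])$alleleB),
        meanDepth = c(rowData(ug)$meanDepth,
                      rowData(sg[soloStacks, ])$meanDepth))
    list(catalog = mergedCatalog, genotypes = merged,
         pairs = data.frame(uneak = locusId(uc)[pairs$uneak],
                            stacks = locusId(sc)[pairs$stacks],
                            mismatches = pairs$mismatches))
}
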