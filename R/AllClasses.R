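#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData rowData<- colData
#' @importFrom Biostrings DNAStringSet width
NULL

#' Per-allele read depths for biallelic GBS markers
#'
#' `AlleleDepthMatrix` holds, for every (locus, accession) cell, the number
#' of sequence reads supporting each of the two alleles of a biallelic SNP
#' discovered from GBS tags.  It extends
#' [SummarizedExperiment::SummarizedExperiment] with two integer assays,
#' `depthA` and `depthB`; rows are loci, columns are accessions.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#'
#' @seealso [readDepthTable()], [callGenotypes()], [simulateReadDepths()]
#' @export
setClass("AlleleDepthMatrix", contains = "SummarizedExperiment")

setValidity("AlleleDepthMatrix", function(object) {
    msg <- character()
    if (!all(c("depthA", "depthB") %in% names(assays(object))))
        msg <- c(msg, "assays 'depthA' and 'depthB' are required")
    else {
        a <- assay(object, "depthA"); b <- assay(object, "depthB")
        if (!identical(dim(a), dim(b)))
            msg <- c(msg, "'depthA' and 'depthB' must have identical shape")
        if (anyNA(a) || anyNA(b))
            msg <- c(msg, "read depths must not be NA (absence is depth 0)")
        else if (min(a, 0L) < 0L || min(b, 0L) < 0L)
            msg <- c(msg, "read depths must be non-negative")
    }
    if (nrow(object) > 0 &&
        (is.null(rownames(object)) || anyDuplicated(rownames(object))))
        msg <- c(msg, "locus identifiers must be present and unique")
    if (ncol(object) > 0 &&
        (is.null(colnames(object)) || anyDuplicated(colnames(object))))
        msg <- c(msg, "accession identifiers must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Construct an AlleleDepthMatrix
#'
#' @param depthA,depthB integer matrices (loci x accessions) of read counts
#'   for allele A and allele B.  Dimnames of `depthA` supply the locus and
#'   accession identifiers.
#' @return An [AlleleDepthMatrix-class] object.
#' @examples
#' a <- matrix(c(10L, 3L, 0L), 1, dimnames = list("TP1", c("s1","s2","s3")))
#' b <- matrix(c(0L, 7L, 0L), 1, dimnames = dimnames(a))
#' AlleleDepthMatrix(a, b)
#' @export
AlleleDepthMatrix <- function(depthA, depthB) {
    storage.mode(depthA) <- "integer"
    storage.mode(depthB) <- "integer"
    dimnames(depthB) <- dimnames(depthA)
    se <- SummarizedExperiment(assays = SimpleList(depthA = depthA,
                                                   depthB = depthB))
    new("AlleleDepthMatrix", se)
}

#' @describeIn AlleleDepthMatrix read depths for allele A.
#' @param x an `AlleleDepthMatrix`.
#' @export
depthA <- function(x) assay(x, "depthA")

#' @describeIn AlleleDepthMatrix read depths for allele B.
#' @export
depthB <- function(x) assay(x, "depthB")

#' @describeIn AlleleDepthMatrix total read depth per cell.
#' @export
totalDepth <- function(x) assay(x, "depthA") + assay(x, "depthB")

#' Genotype calls for biallelic markers with per-locus statistics
#'
#' `GenotypeCalls` stores coded genotypes of a biallelic SNP panel as the
#' dosage of allele B (assay `dosage`: 0 = homozygous A, 1 = heterozygous,
#' 2 = homozygous B, `NA` = missing).  Rows are loci, columns accessions.
#' Per-locus row metadata carry the allele labels (`alleleA`, `alleleB`,
#' single bases when known), which allele is the population major allele
#' (`majorAllele`), the minor allele frequency (`maf`, computed from called
#' genotypes, two allele copies per homozygote), the call rate (`callRate`,
#' fraction of accessions with a non-missing call), the heterozygosity rate
#' (`hetRate`, fraction of non-missing calls that are heterozygous) and,
#' when derived from read depths, the mean depth over covered cells
#' (`meanDepth`).
#'
#' @seealso [callGenotypes()], [filterMarkers()], [minorDosage()]
#' @export
setClass("GenotypeCalls", contains = "SummarizedExperiment")

setValidity("GenotypeCalls", function(object) {
    msg <- character()
    if (!"dosage" %in% names(assays(object)))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- assay(object, "dosage")
        bad <- d[!is.na(d)]
        if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
            msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    }
    need <- c("alleleA", "alleleB", "majorAllele", "maf", "callRate",
              "hetRate")
    miss <- setdiff(need, colnames(rowData(object)))
    if (length(miss))
        msg <- c(msg, paste("missing rowData column(s):",
                            paste(miss, collapse = ", ")))
    else {
        m <- rowData(object)$maf
        if (any(m > 0.5 + 1e-12, na.rm = TRUE))
            msg <- c(msg, "maf must not exceed 0.5")
    }
    if (nrow(object) > 0 &&
        (is.null(rownames(object)) || anyDuplicated(rownames(object))))
        msg <- c(msg, "locus identifiers must be present and unique")
    if (ncol(object) > 0 &&
        (is.null(colnames(object)) || anyDuplicated(colnames(object))))
        msg <- c(msg, "accession identifiers must be present and unique")
    if (length(msg)) msg else TRUE
})

.locusStats <- function(dosage) {
    n <- ncol(dosage)
    notNA <- !is.na(dosage)
    nonmiss <- rowSums(notNA)
    nHet <- rowSums(dosage == 1L, na.rm = TRUE)
    nB2 <- rowSums(dosage == 2L, na.rm = TRUE)
    freqB <- ifelse(nonmiss > 0, (2 * nB2 + nHet) / (2 * nonmiss), NA_real_)
    majorAllele <- ifelse(is.na(freqB) | freqB <= 0.5, "A", "B")
    list(callRate = nonmiss / n,
         hetRate = ifelse(nonmiss > 0, nHet / nonmiss, NA_real_),
         freqB = freqB,
         maf = pmin(freqB, 1 - freqB),
         majorAllele = majorAllele)
}

#' Construct a GenotypeCalls object
#'
#' Per-locus statistics (maf, call rate, heterozygosity, major allele) are
#' computed from the dosage matrix at construction time.
#'
#' @param dosage integer matrix (loci x accessions) of allele-B dosages in
#'   `{0, 1, 2, NA}`, with locus row names and accession column names.
#' @param alleleA,alleleB character vectors of allele bases per locus
#'   (recycled; default `"A"` / `"B"` placeholders when the discovery
#'   alleles are not known).
#' @param meanDepth optional numeric vector: mean read depth per locus over
#'   covered cells.
#' @return A [GenotypeCalls-class] object.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'             dimnames = list(c("L1","L2"), c("s1","s2")))
#' gm <- GenotypeCalls(d, alleleA = c("A","C"), alleleB = c("G","T"))
#' maf(gm)
#' @export
GenotypeCalls <- function(dosage, alleleA = "A", alleleB = "B",
                          meanDepth = NA_real_) {
    storage.mode(dosage) <- "integer"
    st <- .locusStats(dosage)
    rd <- DataFrame(alleleA = rep_len(as.character(alleleA), nrow(dosage)),
                    alleleB = rep_len(as.character(alleleB), nrow(dosage)),
                    majorAllele = st$majorAllele,
                    maf = st$maf, callRate = st$callRate,
                    hetRate = st$hetRate,
                    meanDepth = rep_len(as.numeric(meanDepth), nrow(dosage)),
                    row.names = rownames(dosage))
    se <- SummarizedExperiment(assays = SimpleList(dosage = dosage),
                               rowData = rd)
    new("GenotypeCalls", se)
}

#' Recompute per-locus statistics after subsetting
#'
#' Subsetting a [GenotypeCalls-class] object keeps the original locus
#' statistics; call this to refresh `maf`, `callRate`, `hetRate` and the
#' major-allele assignment from the current dosage matrix.
#'
#' @param gm a `GenotypeCalls` object.
#' @return `gm` with refreshed rowData statistics.
#' @export
recomputeLocusStats <- function(gm) {
    st <- .locusStats(assay(gm, "dosage"))
    rd <- rowData(gm)
    rd$majorAllele <- st$majorAllele
    rd$maf <- st$maf
    rd$callRate <- st$callRate
    rd$hetRate <- st$hetRate
    rowData(gm) <- rd
    gm
}

#' @describeIn GenotypeCalls allele-B dosage matrix (0/1/2/NA).
#' @param x a `GenotypeCalls` object.
#' @export
dosage <- function(x) assay(x, "dosage")

#' Minor-allele dosage coding
#'
#' Returns the genotype matrix coded as the dosage of each locus's minor
#' allele (0 = homozygous major, 1 = heterozygous, 2 = homozygous minor,
#' `NA` = missing).  This is the numeric coding used for PCA, kinship and
#' association scans.
#'
#' @param x a [GenotypeCalls-class] object.
#' @return integer matrix, loci x accessions.
#' @export
minorDosage <- function(x) {
    d <- assay(x, "dosage")
    flip <- rowData(x)$majorAllele == "B"
    d[flip, ] <- 2L - d[flip, , drop = FALSE]
    d
}

#' Genotype call labels
#'
#' @param x a [GenotypeCalls-class] object.
#' @return character matrix with entries `HOM_MAJOR`, `HET`, `HOM_MINOR`
#'   or `MISSING`.
#' @export
callLabels <- function(x) {
    d <- minorDosage(x)
    lab <- matrix("MISSING", nrow(d), ncol(d), dimnames = dimnames(d))
    lab[!is.na(d) & d == 0L] <- "HOM_MAJOR"
    lab[!is.na(d) & d == 1L] <- "HET"
    lab[!is.na(d) & d == 2L] <- "HOM_MINOR"
    lab
}

#' @describeIn GenotypeCalls per-locus minor allele frequency.
#' @export
maf <- function(x) setNames(rowData(x)$maf, rownames(x))

#' @describeIn GenotypeCalls per-locus call rate.
#' @export
callRate <- function(x) setNames(rowData(x)$callRate, rownames(x))

#' @describeIn GenotypeCalls per-locus heterozygosity rate.
#' @export
hetRate <- function(x) setNames(rowData(x)$hetRate, rownames(x))

#' Catalog of SNP-bearing GBS tags
#'
#' A `TagCatalog` records, for each SNP locus discovered by a
#' reference-free GBS pipeline, the consensus tag sequence, the 0-based
#' offset of the SNP within the tag, the two alleles, and the source
#' pipeline dialect: 64-bp tags (`"UNEAK"`) or 80-bp tags (`"STACKS"`).
#' Several records may share one tag sequence (multi-SNP tags).
#'
#' @slot locusId character, unique locus identifiers.
#' @slot tagSeq [Biostrings::DNAStringSet] of consensus tag sequences.
#' @slot snpOffset integer, 0-based SNP position within each tag.
#' @slot alleleA,alleleB character, the two SNP alleles (single bases).
#' @slot source character, `"UNEAK"` or `"STACKS"` per record.
#'
#' @seealso [readTagFasta()], [unionCatalogs()], [firstSnpPerTag()]
#' @export
setClass("TagCatalog",
         representation(locusId = "character", tagSeq = "DNAStringSet",
                        snpOffset = "integer", alleleA = "character",
                        alleleB = "character", source = "character"))

setValidity("TagCatalog", function(object) {
    n <- length(object@locusId)
    msg <- character()
    if (length(object@tagSeq) != n || length(object@snpOffset) != n ||
        length(object@alleleA) != n || length(object@alleleB) != n ||
        length(object@source) != n)
        msg <- c(msg, "all slots must have equal length")
    if (anyDuplicated(object@locusId))
        msg <- c(msg, "locus identifiers must be unique")
    if (n) {
        if (any(object@snpOffset < 0L) ||
            any(object@snpOffset >= width(object@tagSeq)))
            msg <- c(msg, "snpOffset must lie within the tag")
        if (!all(unlist(strsplit(as.character(object@tagSeq), "")) %in%
                 c("A", "C", "G", "T")))
            msg <- c(msg, "tag sequences must be over {A,C,G,T}")
        if (any(object@alleleA == object@alleleB))
            msg <- c(msg, "the two alleles of a SNP must differ")
        if (!all(object@source %in% c("UNEAK", "STACKS")))
            msg <- c(msg, "source must be 'UNEAK' or 'STACKS'")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TagCatalog
#'
#' @param locusId character vector of unique locus identifiers.
#' @param tagSeq DNA tag sequences (character or `DNAStringSet`).
#' @param snpOffset integer vector of 0-based SNP offsets within tags.
#' @param alleleA,alleleB single-base alleles per locus.
#' @param source `"UNEAK"`, `"STACKS"`, or `NA` to infer from tag length
#'   (64 bp is the UNEAK dialect, 80 bp the Stacks dialect).
#' @return A [TagCatalog-class] object.
#' @export
TagCatalog <- function(locusId, tagSeq, snpOffset, alleleA, alleleB,
                       source = NA_character_) {
    tagSeq <- DNAStringSet(tagSeq)
    names(tagSeq) <- NULL
    n <- length(locusId)
    source <- rep_len(source, n)
    infer <- is.na(source)
    if (any(infer))
        source[infer] <- ifelse(width(tagSeq)[infer] >= 80L,
                                "STACKS", "UNEAK")
    new("TagCatalog", locusId = as.character(locusId), tagSeq = tagSeq,
        snpOffset = as.integer(snpOffset),
        alleleA = as.character(alleleA), alleleB = as.character(alleleB),
        source = source)
}

#' @describeIn TagCatalog number of SNP records.
#' @param x a `TagCatalog`.
#' @export
setMethod("length", "TagCatalog", function(x) length(x@locusId))

#' @describeIn TagCatalog subset records.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "TagCatalog", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@locusId)
    initialize(x, locusId = x@locusId[i], tagSeq = x@tagSeq[i],
               snpOffset = x@snpOffset[i], alleleA = x@alleleA[i],
               alleleB = x@alleleB[i], source = x@source[i])
})

#' @describeIn TagCatalog locus identifiers.
#' @export
locusId <- function(x) x@locusId

#' @describeIn TagCatalog tag sequences as a `DNAStringSet` named by locus.
#' @export
tagSequences <- function(x) setNames(x@tagSeq, x@locusId)

#' @describeIn TagCatalog 0-based SNP offsets, named by locus.
#' @export
snpOffset <- function(x) setNames(x@snpOffset, x@locusId)

#' @describeIn TagCatalog data.frame of (alleleA, alleleB) per locus.
#' @export
snpAlleles <- function(x)
    data.frame(locusId = x@locusId, alleleA = x@alleleA,
               alleleB = x@alleleB)

#' @describeIn TagCatalog source pipeline per record.
#' @export
tagSource <- function(x) setNames(x@source, x@locusId)

setMethod("show", "TagCatalog", function(object) {
    cat("TagCatalog with", length(object), "SNP record(s)\n")
    src <- table(object@source)
    if (length(src))
        cat("  source:", paste(names(src), src, sep = "=", collapse = ", "),
            "\n")
    if (length(object)) {
        k <- seq_len(min(3L, length(object)))
        cat("  e.g.", paste0(object@locusId[k], " (offset ",
                             object@snpOffset[k], ", ",
                             object@alleleA[k], "/", object@alleleB[k], ")",
                             collapse = "; "), "\n")
    }
})

#' Validate a group-membership table
#'
#' Group tables map accessions to genetic-group labels, with an
#' availability flag used as the eligibility mask for core selection and
#' an optional STRUCTURE-style membership coefficient carried as metadata.
#'
#' @param groups data.frame with columns `accession`, `group`, and
#'   optionally `available` (logical, default `TRUE`) and `membershipQ`
#'   (numeric in `[0, 1]`).
#' @return the normalized data.frame (missing optional columns filled).
#' @export
asGroupTable <- function(groups) {
    stopifnot(is.data.frame(groups),
              all(c("accession", "group") %in% names(groups)))
    if (anyDuplicated(groups$accession))
        stop("each accession may appear at most once in a group table")
    if (is.null(groups$available)) groups$available <- TRUE
    if (is.null(groups$membershipQ)) groups$membershipQ <- NA_real_
    q <- groups$membershipQ
    if (any(q < 0 | q > 1, na.rm = TRUE))
        stop("membershipQ must lie in [0, 1]")
    groups[c("accession", "group", "available", "membershipQ")]
}
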