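#' @importFrom Biostrings readDNAStringSet writeXStringSet
#' @importFrom utils read.csv write.csv
NULL

#' Read a per-allele read-depth table
#'
#' Two CSV dialects are supported.  `"long"` has a header and one row per
#' cell: `locus,accession,countA,countB`.  `"wide"` has a `locus` column
#' followed by two columns per accession named `<accession>.A` and
#' `<accession>.B`.  Cells absent from a long-format file are taken as
#' unobserved, i.e. depth (0, 0).
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"`.
#' @return an [AlleleDepthMatrix-class].
#' @export
readDepthTable <- function(path, dialect = c("long", "wide")) {
    dialect <- match.arg(dialect)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L)
        stop("no records in depth table '", path, "'")
    if (dialect == "long") {
        fields <- strsplit(lines, ",", fixed = TRUE)
        nf <- lengths(fields)
        if (any(nf != 4L))
            stop("malformed depth-table row at line ",
                 which(nf != 4L)[1L], " of '", path, "'")
        body <- fields[-1L]
        locus <- vapply(body, `[`, "", 1L)
        acc <- vapply(body, `[`, "", 2L)
        ca <- suppressWarnings(as.numeric(vapply(body, `[`, "", 3L)))
        cb <- suppressWarnings(as.numeric(vapply(body, `[`, "", 4L)))
        bad <- is.na(ca) | is.na(cb) | ca < 0 | cb < 0 |
            ca != round(ca) | cb != round(cb)
        if (any(bad))
            stop("invalid read count at line ", which(bad)[1L] + 1L,
                 " of '", path, "'")
        key <- paste(locus, acc, sep = "\r")
        if (anyDuplicated(key)) {
            d <- key[duplicated(key)][1L]
            stop("duplicate (locus, accession) cell: ",
                 sub("\r", ", ", d, fixed = TRUE))
        }
        loci <- unique(locus); accs <- unique(acc)
        a <- matrix(0L, length(loci), length(accs),
                    dimnames = list(loci, accs))
        b <- a
        idx <- cbind(match(locus, loci), match(acc, accs))
        a[idx] <- as.integer(ca)
        b[idx] <- as.integer(cb)
        AlleleDepthMatrix(a, b)
    } else {
        df <- read.csv(path, check.names = FALSE)
        if (names(df)[1L] != "locus")
            stop("wide depth table must start with a 'locus' column")
        if (anyDuplicated(df$locus))
            stop("duplicate locus in wide depth table")
        cols <- names(df)[-1L]
        accA <- sub("\\.A$", "", grep("\\.A$", cols, value = TRUE))
        accB <- sub("\\.B$", "", grep("\\.B$", cols, value = TRUE))
        if (!setequal(accA, accB) || length(cols) != 2L * length(accA))
            stop("wide depth table needs paired <accession>.A/.B columns")
        m <- as.matrix(df[-1L])
        if (anyNA(m) || any(m < 0) || any(m != round(m)))
            stop("invalid read count in wide depth table")
        a <- m[, paste0(accA, ".A"), drop = FALSE]
        b <- m[, paste0(accA, ".B"), drop = FALSE]
        dimnames(a) <- dimnames(b) <- list(df$locus, accA)
        AlleleDepthMatrix(a, b)
    }
}

.catalogAlleles <- function(gm, catalog) {
    idx <- match(rownames(gm), locusId(catalog))
    if (anyNA(idx))
        stop("locus absent from tag catalog: ",
             rownames(gm)[is.na(idx)][1L])
    list(A = catalog@alleleA[idx], B = catalog@alleleB[idx],
         pos = catalog@snpOffset[idx] + 1L)
}

#' Write genotype calls in HapMap format
#'
#' Emits the standard 11-column HapMap header (`rs#`, `alleles`, `chrom`,
#' `pos`, `strand`, `assembly#`, `center`, `protLSID`, `assayLSID`,
#' `panelLSID`, `QCcode`) followed by one column per accession.  Diploid
#' genotypes are written as two nucleotide characters with the
#' heterozygote's bases in alphabetical order; missing calls are `NN`.
#' Tags carry no genome coordinates, so `chrom` is `0` and `pos` is the
#' 1-based SNP offset within the tag.
#'
#' @param gm a [GenotypeCalls-class]; its loci must all be present in
#'   `catalog`, which supplies the allele bases.
#' @param catalog a [TagCatalog-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHapMap <- function(gm, catalog, path) {
    al <- .catalogAlleles(gm, catalog)
    d <- dosage(gm)
    geno <- matrix("NN", nrow(d), ncol(d))
    for (i in seq_len(nrow(d))) {
        het <- paste0(pmin(al$A[i], al$B[i]), pmax(al$A[i], al$B[i]))
        g <- c(paste0(al$A[i], al$A[i]), het, paste0(al$B[i], al$B[i]))
        di <- d[i, ]
        geno[i, !is.na(di)] <- g[di[!is.na(di)] + 1L]
    }
    hdr <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
             "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
             colnames(d))
    rows <- if (nrow(d)) {
        meta <- cbind(rownames(d), paste0(al$A, "/", al$B), "0", al$pos,
                      "+", "NA", "NA", "NA", "NA", "NA", "NA")
        apply(cbind(meta, geno), 1L, paste, collapse = "\t")
    } else character(0)
    writeLines(c(paste(hdr, collapse = "\t"), rows), path)
    invisible(path)
}

#' Read a HapMap genotype file
#'
#' Counterpart of [writeHapMap()]: allele orientation is taken from the
#' `alleles` column (`A/B`), and dosages count copies of allele B.
#'
#' @param path HapMap file.
#' @return a [GenotypeCalls-class].
#' @export
readHapMap <- function(path) {
    lines <- readLines(path)
    if (!length(lines)) stop("empty HapMap file")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    hdr <- fields[[1L]]
    if (length(hdr) < 11L || hdr[1L] != "rs#")
        stop("not a HapMap file: ", path)
    accs <- hdr[-seq_len(11L)]
    body <- fields[-1L]
    loci <- vapply(body, `[`, "", 1L)
    alleles <- strsplit(vapply(body, `[`, "", 2L), "/", fixed = TRUE)
    aA <- vapply(alleles, `[`, "", 1L)
    aB <- vapply(alleles, `[`, "", 2L)
    d <- matrix(NA_integer_, length(loci), length(accs),
                dimnames = list(loci, accs))
    for (i in seq_along(body)) {
        g <- body[[i]][-seq_len(11L)]
        nB <- vapply(strsplit(g, ""), function(ch) sum(ch == aB[i]), 0L)
        nA <- vapply(strsplit(g, ""), function(ch) sum(ch == aA[i]), 0L)
        ok <- nA + nB == 2L
        d[i, ok] <- nB[ok]
    }
    GenotypeCalls(d, alleleA = aA, alleleB = aB)
}

#' Write genotype calls as VCF 4.2
#'
#' Genotypes only (`FORMAT` = `GT`): allele A is `REF`, allele B `ALT`;
#' dosages map to `0/0`, `0/1`, `1/1` and missing to `./.`.  `CHROM` is
#' the tag locus identifier and `POS` the 1-based SNP offset within the
#' tag (tags have no genome coordinates).
#'
#' @inheritParams writeHapMap
#' @return `path`, invisibly.
#' @export
writeVCF <- function(gm, catalog, path) {
    al <- .catalogAlleles(gm, catalog)
    d <- dosage(gm)
    gt <- matrix("./.", nrow(d), ncol(d))
    gt[!is.na(d) & d == 0L] <- "0/0"
    gt[!is.na(d) & d == 1L] <- "0/1"
    gt[!is.na(d) & d == 2L] <- "1/1"
    meta <- c("##fileformat=VCFv4.2",
              "##source=GBSpanel",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", colnames(d)),
                    collapse = "\t"))
    rows <- if (nrow(d)) {
        fix <- cbind(rownames(d), al$pos, rownames(d), al$A, al$B, ".",
                     ".", ".", "GT")
        apply(cbind(fix, gt), 1L, paste, collapse = "\t")
    } else character(0)
    writeLines(c(meta, rows), path)
    invisible(path)
}

#' Read a VCF genotype file
#'
#' Uses \pkg{vcfR} to parse the file; only the `GT` field is used.
#' Dosages count copies of the `ALT` allele (allele B).
#'
#' @param path VCF file.
#' @return a [GenotypeCalls-class].
#' @export
readVCF <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    fix <- vcfR::getFIX(v)
    loci <- unname(fix[, "ID"])
    d <- matrix(NA_integer_, nrow(gt), ncol(gt),
                dimnames = list(loci, colnames(gt)))
    d[gt %in% c("0/0", "0|0")] <- 0L
    d[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    d[gt %in% c("1/1", "1|1")] <- 2L
    GenotypeCalls(d, alleleA = unname(fix[, "REF"]),
                  alleleB = unname(fix[, "ALT"]))
}

#' Read a tag-catalog FASTA file
#'
#' Headers follow the grammar `locusID|offset|A/B`, with `offset` the
#' 0-based SNP position within the tag and `A/B` the two SNP alleles.
#' The source pipeline is inferred from the tag length: 64 bp is the
#' UNEAK dialect, 80 bp the Stacks dialect.
#'
#' @param path FASTA file.
#' @return a [TagCatalog-class].
#' @export
readTagFasta <- function(path) {
    seqs <- readDNAStringSet(path)
    if (!length(seqs)) stop("no records in '", path, "'")
    parts <- strsplit(names(seqs), "|", fixed = TRUE)
    if (any(lengths(parts) != 3L))
        stop("tag FASTA headers must follow 'locusID|offset|A/B'")
    ids <- vapply(parts, `[`, "", 1L)
    if (anyDuplicated(ids))
        stop("duplicate locus in tag FASTA: ", ids[duplicated(ids)][1L])
    off <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    al <- strsplit(vapply(parts, `[`, "", 3L), "/", fixed = TRUE)
    if (any(is.na(off)) || any(lengths(al) != 2L))
        stop("tag FASTA headers must follow 'locusID|offset|A/B'")
    if (any(off >= width(seqs)))
        stop("SNP offset beyond tag length for locus ",
             ids[off >= width(seqs)][1L])
    TagCatalog(ids, seqs, off,
               vapply(al, `[`, "", 1L), vapply(al, `[`, "", 2L))
}

#' Write a tag catalog as FASTA
#'
#' Inverse of [readTagFasta()], using the same header grammar.
#'
#' @param catalog a [TagCatalog-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTagFasta <- function(catalog, path) {
    seqs <- catalog@tagSeq
    names(seqs) <- paste0(catalog@locusId, "|", catalog@snpOffset, "|",
                          catalog@alleleA, "/", catalog@alleleB)
    writeXStringSet(seqs, path)
    invisible(path)
}

#' Read a group-membership CSV
#'
#' Expects columns `accession,group` and optionally `available` and
#' `membershipQ`; see [asGroupTable()].
#'
#' @param path CSV file.
#' @return a normalized group-table data.frame.
#' @export
readGroupTable <- function(path) {
    asGroupTable(read.csv(path))
}
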