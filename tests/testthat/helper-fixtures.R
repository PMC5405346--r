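# Small in-code fixtures and independent brute-force oracles.

# dosage matrix with auto dimnames -> GenotypeCalls
makeGm <- function(d, ...) {
    d <- as.matrix(d)
    if (is.null(rownames(d)))
        rownames(d) <- sprintf("L%03d", seq_len(nrow(d)))
    if (is.null(colnames(d)))
        colnames(d) <- sprintf("S%02d", seq_len(ncol(d)))
    GenotypeCalls(d, ...)
}

randomGm <- function(nLoci, nAcc, missRate = 0.2, seed = 1) {
    set.seed(seed)
    d <- matrix(sample(0:2, nLoci * nAcc, replace = TRUE,
                       prob = c(0.5, 0.1, 0.4)), nLoci, nAcc)
    d[runif(length(d)) < missRate] <- NA
    makeGm(d)
}

# exhaustive double-loop private-allele count (oracle for uniqueAlleles)
bruteUniqueAlleles <- function(gm, group, comparison) {
    d <- dosage(gm)
    count <- 0L
    for (i in seq_len(nrow(d))) {
        for (allele in c("A", "B")) {
            seen <- function(accs) {
                any(vapply(accs, function(a) {
                    g <- d[i, a]
                    if (is.na(g)) return(FALSE)
                    if (allele == "A") g <= 1L else g >= 1L
                }, TRUE))
            }
            if (seen(group) && !seen(comparison)) count <- count + 1L
        }
    }
    count
}

# set-based allele coverage (oracle for alleleCoverage)
bruteCoverage <- function(gm, subset) {
    alleleSet <- function(accs) {
        d <- dosage(gm)[, accs, drop = FALSE]
        out <- character(0)
        for (i in seq_len(nrow(d))) {
            g <- d[i, ]
            if (any(!is.na(g) & g <= 1L))
                out <- c(out, paste0(rownames(d)[i], "_A"))
            if (any(!is.na(g) & g >= 1L))
                out <- c(out, paste0(rownames(d)[i], "_B"))
        }
        out
    }
    full <- alleleSet(colnames(gm))
    length(intersect(alleleSet(subset), full)) / length(full)
}

# random tags carrying a given allele base at a fixed 0-based offset
.randomTagFor <- function(n, alleleA, offset = 10L, len = 64L) {
    tags <- vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), "")
    substr(tags, offset + 1L, offset + 1L) <- alleleA
    tags
}

# run the full simulate -> depths -> call chain
simulateCalled <- function(cfg) {
    tr <- simulatePopulation(cfg)
    adm <- simulateReadDepths(tr)
    list(truth = tr, adm = adm, gm = callGenotypes(adm))
}

# genotype matrices matched to the two simulated catalogs (the Stacks
# pipeline re-calls the same accessions under its own locus ids)
catalogGenotypes <- function(truth, cats) {
    gmAll <- truth$genotypes
    ugm <- gmAll[locusId(cats$uneak), ]
    sIds <- locusId(cats$stacks)
    sd <- dosage(gmAll)[sub("^ST", "L", sIds), , drop = FALSE]
    rownames(sd) <- sIds
    list(uneak = list(catalog = cats$uneak, genotypes = ugm),
         stacks = list(catalog = cats$stacks,
                       genotypes = GenotypeCalls(sd)))
}
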