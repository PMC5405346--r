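#' Missing-data score of accessions
#'
#' Each accession contributes `1 - (proportion of missing genotypes)`;
#' the score of a group of accessions is the sum of its members'
#' scores.  Scores are the currency of the missing-data-standardized
#' downsampling used for private-allele comparisons.
#'
#' @param gm a [GenotypeCalls-class].
#' @param accessions accession identifiers (default: all).
#' @return named numeric vector of per-accession scores.
#' @export
accessionScore <- function(gm, accessions = colnames(gm)) {
    bad <- setdiff(accessions, colnames(gm))
    if (length(bad)) stop("unknown accession: ", bad[1L])
    d <- dosage(gm)[, accessions, drop = FALSE]
    1 - colSums(is.na(d)) / nrow(d)
}

#' Downsampling specification for private-allele comparisons
#'
#' Groups are equalized for data content, not size: accessions are added
#' in random order until the cumulative score reaches
#' `scoreThreshold - tolerance`; the subset is accepted if its score is
#' at most `scoreThreshold + tolerance`, otherwise a new random order is
#' tried.
#'
#' @param scoreThreshold target group score; `NULL` (default) means the
#'   minimum total group score across the groups being compared — the
#'   score of the group with the least data.
#' @param tolerance acceptance half-width around the threshold.
#' @param nIterations number of downsampling iterations to average over.
#' @param seed integer seed.
#' @return a `DownsampleSpec` list.
#' @export
downsampleSpec <- function(scoreThreshold = NULL, tolerance = 0.5,
                           nIterations = 100L, seed = 1L) {
    stopifnot(is.null(scoreThreshold) || scoreThreshold > 0,
              tolerance >= 0, nIterations >= 1L)
    structure(list(scoreThreshold = scoreThreshold,
                   tolerance = tolerance,
                   nIterations = as.integer(nIterations),
                   seed = as.integer(seed)),
              class = "DownsampleSpec")
}

#' Downsample a group to a target missing-data score
#'
#' Draws accessions uniformly at random without replacement until the
#' cumulative score ([accessionScore()]) reaches
#' `threshold - tolerance`; the draw is accepted if the cumulative score
#' does not exceed `threshold + tolerance`, and restarted with a fresh
#' order otherwise (a single addition can overshoot the band).
#'
#' @param gm a [GenotypeCalls-class].
#' @param members accession identifiers of the group.
#' @param threshold target score.
#' @param tolerance acceptance half-width.
#' @param maxRestarts restart budget before giving up.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return character vector: the accepted accession subset.
#' @export
downsampleGroup <- function(gm, members, threshold, tolerance = 0.5,
                            maxRestarts = 1000L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    sc <- accessionScore(gm, members)
    if (sum(sc) < threshold - tolerance)
        stop("group score ", round(sum(sc), 3),
             " cannot reach threshold ", threshold, " - ", tolerance)
    for (r in seq_len(maxRestarts)) {
        ord <- sample(members)
        cum <- cumsum(sc[ord])
        k <- which(cum >= threshold - tolerance)[1L]
        if (cum[k] <= threshold + tolerance)
            return(ord[seq_len(k)])
    }
    stop("downsampling failed after ", maxRestarts, " restarts: no ",
         "random order lands in [", threshold - tolerance, ", ",
         threshold + tolerance, "]; widen the tolerance")
}

# logical (loci x accessions) presence of allele A / allele B per cell
.allelePresence <- function(d) {
    list(A = !is.na(d) & d <= 1L, B = !is.na(d) & d >= 1L)
}

.observedAlleles <- function(pres, accessions) {
    c(rowSums(pres$A[, accessions, drop = FALSE]) > 0,
      rowSums(pres$B[, accessions, drop = FALSE]) > 0)
}

#' Count alleles private to a group
#'
#' Over all loci and both alleles per locus, counts the alleles that are
#' observed (at least one non-missing call carrying at least one copy)
#' in `group` but not observed in `comparison`.  Missing calls carry no
#' alleles.
#'
#' @param gm a [GenotypeCalls-class].
#' @param group,comparison accession identifier vectors (need not be
#'   disjoint).
#' @return integer count of private alleles.
#' @export
uniqueAlleles <- function(gm, group, comparison) {
    if (!length(group)) stop("empty group")
    pres <- .allelePresence(dosage(gm))
    inG <- .observedAlleles(pres, group)
    inC <- .observedAlleles(pres, comparison)
    sum(inG & !inC)
}

#' Group-wise private-allele counts standardized for missing data
#'
#' Repeats, `nIterations` times: downsample every genetic group to a
#' common missing-data score, then count the alleles observed in each
#' focal group's subset but absent from each comparison set's subset.
#' Group sizes and missingness therefore no longer drive the counts.
#' The default threshold is the total score of the group with the least
#' data.
#'
#' @param gm a [GenotypeCalls-class].
#' @param groups a group table ([asGroupTable()]).
#' @param comparisons named list defining the comparison sets, each
#'   element a character vector of group labels whose (downsampled)
#'   members are pooled; the reserved value `"others"` denotes, for each
#'   focal group, all other groups pooled.  Default:
#'   `list(AllOthers = "others")`.
#' @param spec a [downsampleSpec()].
#' @param focal group labels to report (default: all).
#' @param downsampleComparison if `FALSE`, comparison sets use all their
#'   members rather than the downsampled subsets.
#' @return data.frame with columns `group`, `comparison`,
#'   `meanUnique`, `sdUnique`; the per-iteration counts are attached as
#'   attribute `"iterations"` (array group x comparison x iteration).
#' @export
standardizedUniqueAlleles <- function(gm, groups,
                                      comparisons = list(AllOthers = "others"),
                                      spec = downsampleSpec(),
                                      focal = NULL,
                                      downsampleComparison = TRUE) {
    groups <- asGroupTable(groups)
    groups <- groups[groups$accession %in% colnames(gm), ]
    labels <- unique(groups$group)
    if (is.null(focal)) focal <- labels
    members <- split(groups$accession, groups$group)[labels]
    totals <- vapply(members, function(m) sum(accessionScore(gm, m)), 0)
    thr <- if (is.null(spec$scoreThreshold)) min(totals)
           else spec$scoreThreshold
    set.seed(spec$seed)
    counts <- array(NA_real_,
                    dim = c(length(focal), length(comparisons),
                            spec$nIterations),
                    dimnames = list(focal, names(comparisons), NULL))
    for (it in seq_len(spec$nIterations)) {
        sub <- lapply(labels, function(lab)
            tryCatch(downsampleGroup(gm, members[[lab]], thr,
                                     spec$tolerance),
                     error = function(e)
                         stop("group '", lab, "': ", conditionMessage(e),
                              call. = FALSE)))
        names(sub) <- labels
        pool <- if (downsampleComparison) sub else members
        for (g in focal) {
            for (cn in names(comparisons)) {
                comp <- comparisons[[cn]]
                labs <- if (identical(comp, "others"))
                    setdiff(labels, g) else comp
                counts[g, cn, it] <-
                    uniqueAlleles(gm, sub[[g]],
                                  unique(unlist(pool[labs])))
            }
        }
    }
    out <- expand.grid(group = focal, comparison = names(comparisons),
                       stringsAsFactors = FALSE)
    out$meanUnique <- mapply(function(g, cn) mean(counts[g, cn, ]),
                             out$group, out$comparison)
    out$sdUnique <- mapply(function(g, cn) sd(counts[g, cn, ]),
                           out$group, out$comparison)
    attr(out, "iterations") <- counts
    out
}

#' Probabilistic PCA of a genotype matrix with missing entries
#'
#' Fits probabilistic PCA by expectation-maximization, treating missing
#' genotypes as latent: genotypes are coded as minor-allele dosage
#' (0/1/2), accessions are observations, loci variables.  Missing cells
#' are iteratively re-imputed from the current low-rank model; after
#' convergence the completed matrix is decomposed by SVD so components
#' are orthogonal, ordered by explained variance, and equal to ordinary
#' PCA when no data are missing.  The sign convention makes the
#' largest-magnitude loading of each component positive.
#'
#' @param gm a [GenotypeCalls-class].
#' @param nComponents number of components (must be less than both
#'   matrix dimensions).
#' @param maxIter maximum EM iterations.
#' @param tol relative-change convergence tolerance on the model's
#'   residual variance and observed-data reconstruction error.
#' @param seed seed for the random initialization of the loadings.
#' @return list with `scores` (accessions x components), `loadings`
#'   (loci x components), `varExplained` (fraction per component),
#'   `center`, `converged` flag, `nIter` and `trace` (observed-data
#'   reconstruction error per EM iteration).
#' @export
ppcaGenotypes <- function(gm, nComponents = 10L, maxIter = 1000L,
                          tol = 1e-6, seed = 1L) {
    X <- t(minorDosage(gm)) * 1.0
    keep <- colSums(!is.na(X)) > 0L
    if (!all(keep)) {
        warning(sum(!keep), " locus/loci with no calls dropped")
        X <- X[, keep, drop = FALSE]
    }
    n <- nrow(X); d <- ncol(X)
    k <- as.integer(nComponents)
    if (k >= min(n, d))
        stop("nComponents must be smaller than both matrix dimensions")
    obs <- !is.na(X)
    mu <- colMeans(X, na.rm = TRUE)
    Xc <- sweep(X, 2L, mu)
    trace <- numeric(0)
    converged <- TRUE
    nIter <- 0L
    if (any(!obs)) {
        Xc[!obs] <- 0
        set.seed(seed)
        W <- matrix(rnorm(d * k), d, k) * 0.1
        ss <- 1
        rssOld <- Inf
        converged <- FALSE
        for (iter in seq_len(maxIter)) {
            M <- crossprod(W) + diag(ss, k)
            Minv <- solve(M)
            Ez <- Xc %*% W %*% Minv
            Ezz <- n * ss * Minv + crossprod(Ez)
            W <- crossprod(Xc, Ez) %*% solve(Ezz)
            recon <- Ez %*% t(W)
            ss <- max((sum(Xc^2) - 2 * sum(recon * Xc) +
                       sum(Ezz * crossprod(W))) / (n * d), 1e-12)
            rss <- sum((Xc[obs] - recon[obs])^2)
            trace <- c(trace, rss)
            # EM for the missing entries: impute from the current model
            Xc[!obs] <- recon[!obs]
            shift <- colMeans(Xc)
            Xc <- sweep(Xc, 2L, shift)
            mu <- mu + shift
            nIter <- iter
            if (is.finite(rssOld) &&
                abs(rssOld - rss) <= tol * max(rssOld, 1e-12)) {
                converged <- TRUE
                break
            }
            rssOld <- rss
        }
        if (!converged)
            warning("probabilistic PCA did not converge in ", maxIter,
                    " iterations")
    }
    sv <- svd(Xc, nu = k, nv = k)
    scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
    loadings <- sv$v
    for (c in seq_len(k)) {
        j <- which.max(abs(loadings[, c]))
        if (loadings[j, c] < 0) {
            loadings[, c] <- -loadings[, c]
            scores[, c] <- -scores[, c]
        }
    }
    dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(k)))
    dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(k)))
    list(scores = scores, loadings = loadings,
         varExplained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
         center = mu, converged = converged, nIter = nIter,
         trace = trace)
}
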