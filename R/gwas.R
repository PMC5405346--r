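#' @importFrom stats lm.wfit coef
NULL

#' VanRaden genomic relationship matrix
#'
#' Computes the genomic kinship K = Z Z' / (2 * sum(p * (1 - p))) from
#' minor-allele dosages, where Z is the dosage matrix centered at twice
#' the allele frequency of each locus and missing dosages are imputed
#' at the locus mean.  Monomorphic loci carry no information and are
#' dropped.
#'
#' @param gm a [GenotypeCalls-class] (ideally filtered).
#' @return symmetric positive semi-definite accessions x accessions
#'   matrix.
#' @export
vanRadenKinship <- function(gm) {
    M <- t(minorDosage(gm)) * 1.0            # accessions x loci
    p <- colMeans(M, na.rm = TRUE) / 2
    poly <- !is.na(p) & p > 0 & p < 1
    if (sum(poly) < 2L)
        stop("kinship needs at least two polymorphic loci")
    M <- M[, poly, drop = FALSE]
    p <- p[poly]
    for (j in which(colSums(is.na(M)) > 0L))
        M[is.na(M[, j]), j] <- 2 * p[j]
    Z <- sweep(M, 2L, 2 * p)
    K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
    dimnames(K) <- list(rownames(M), rownames(M))
    K
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return `alpha / m`.
#' @examples
#' bonferroniThreshold(0.05, 66591)  # ~7.5e-7
#' @export
bonferroniThreshold <- function(alpha = 0.05, m) {
    stopifnot(alpha > 0, alpha < 1)
    if (m < 1) stop("number of tests must be at least 1")
    alpha / m
}

# Profile (restricted) log-likelihood machinery on the eigenbasis of K.
# lambda = sigma2_g / sigma2_e; weights are 1 / (lambda * d_i + 1).
.mmProfileLL <- function(logLambda, ys, Xs, d, reml = TRUE) {
    lambda <- exp(logLambda)
    w <- 1 / (lambda * d + 1)
    n <- length(ys); q <- ncol(Xs)
    fit <- lm.wfit(Xs, ys, w)
    rss <- sum(w * fit$residuals^2)
    if (reml) {
        s2 <- rss / (n - q)
        XtWX <- crossprod(Xs * sqrt(w))
        XtX <- crossprod(Xs)
        as.numeric(-0.5 * ((n - q) * (log(2 * pi * s2) + 1) +
                           sum(log(lambda * d + 1)) +
                           determinant(XtWX)$modulus -
                           determinant(XtX)$modulus))
    } else {
        s2 <- rss / n
        -0.5 * (n * (log(2 * pi * s2) + 1) + sum(log(lambda * d + 1)))
    }
}

.mmFit <- function(ys, Xs, d, reml = TRUE, logLambdaRange = c(-10, 10)) {
    opt <- optimize(function(r) .mmProfileLL(r, ys, Xs, d, reml),
                    interval = logLambdaRange, maximum = TRUE,
                    tol = 1e-8)
    # compare against the boundaries of the search interval
    cand <- c(opt$maximum, logLambdaRange)
    ll <- c(opt$objective,
            vapply(logLambdaRange, .mmProfileLL, 0, ys = ys, Xs = Xs,
                   d = d, reml = reml))
    r <- cand[which.max(ll)]
    lambda <- exp(r)
    w <- 1 / (lambda * d + 1)
    fit <- lm.wfit(Xs, ys, w)
    rss <- sum(w * fit$residuals^2)
    n <- length(ys); q <- ncol(Xs)
    s2e <- rss / (if (reml) n - q else n)
    list(lambda = lambda, sigmaE2 = s2e, sigmaG2 = lambda * s2e,
         logLik = max(ll), weights = w)
}

.alignScan <- function(y, gm, K, pcs) {
    if (is.data.frame(y)) y <- setNames(y$phenotype, y$accession)
    if (is.null(names(y)))
        stop("phenotypes must be named by accession")
    acc <- names(y)
    if (!is.null(gm)) acc <- intersect(acc, colnames(gm))
    acc <- acc[!is.na(y[acc])]
    if (!is.null(K)) {
        if (is.null(rownames(K)))
            stop("kinship matrix must carry accession names")
        acc <- intersect(acc, rownames(K))
    }
    if (!is.null(pcs)) acc <- intersect(acc, rownames(pcs))
    if (length(acc) < 3L) stop("too few accessions with phenotypes")
    list(acc = acc, y = as.numeric(y[acc]))
}

#' Choose the number of structure PCs by BIC
#'
#' Fits the null mixed model (phenotype on intercept plus the first `j`
#' principal components, polygenic covariance proportional to `K`) by
#' maximum likelihood for `j = 0, ..., maxPcs`, and returns the `j`
#' minimizing `BIC = -2 logLik + nParams log(n)`, where the parameter
#' count includes the fixed effects and the two variance components.
#'
#' @param y named binary (0/1) phenotype vector, or a data.frame with
#'   columns `accession` and `phenotype`; `NA` phenotypes are dropped.
#' @param pcs accessions x components score matrix ordered by explained
#'   variance (e.g. from [ppcaGenotypes()]).
#' @param K kinship matrix, or `NULL` for independent residuals.
#' @param maxPcs largest number of PCs to consider.
#' @return integer: the BIC-optimal number of leading PCs.
#' @export
selectPcsBIC <- function(y, pcs, K = NULL, maxPcs = ncol(pcs)) {
    al <- .alignScan(y, gm = NULL, K = K, pcs = pcs)
    # gm not needed here: alignment on y/pcs/K only
    n <- length(al$acc)
    if (n <= maxPcs + 3L)
        stop("too few observations for ", maxPcs, " candidate PCs")
    if (!is.null(K)) {
        eig <- eigen(K[al$acc, al$acc], symmetric = TRUE)
        d <- pmax(eig$values, 0)
        U <- eig$vectors
        ys <- drop(crossprod(U, al$y))
    } else {
        d <- rep(0, n); U <- NULL; ys <- al$y
    }
    bic <- vapply(0:maxPcs, function(j) {
        X <- cbind(Intercept = 1, pcs[al$acc, seq_len(j), drop = FALSE])
        Xs <- if (is.null(U)) X else crossprod(U, X)
        fit <- .mmFit(ys, Xs, d, reml = FALSE)
        -2 * fit$logLik + (ncol(X) + 2) * log(n)
    }, 0)
    (0:maxPcs)[which.min(bic)]
}

#' Single-marker mixed-linear-model association scan
#'
#' Tests each SNP for association with a (binary, 0/1-coded) trait under
#' the model `y = mu + PCs b + x beta + u + e`, with polygenic effect
#' `u ~ (0, sigma2_g K)` and residual `e ~ (0, sigma2_e I)`.  Variance
#' components are estimated once on the null model by REML via the
#' eigendecomposition of `K` and a bounded search over
#' `log(sigma2_g / sigma2_e)` (the P3D/EMMAX approximation); every SNP
#' is then tested by generalized least squares at that fixed ratio with
#' a Wald t-test.  With `K = NULL` the scan reduces exactly to ordinary
#' least squares.  Missing genotypes are imputed at the locus mean;
#' SNPs monomorphic after phenotype alignment are skipped with an `NA`
#' result.
#'
#' @param y named phenotype vector (or data.frame `accession`,
#'   `phenotype`); `NA`s are excluded.
#' @param gm a [GenotypeCalls-class]; the SNP predictor is minor-allele
#'   dosage.
#' @param K kinship matrix from [vanRadenKinship()], or `NULL`.
#' @param pcs optional accessions x components covariate matrix.
#' @param nPcs number of leading columns of `pcs` to include.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param method `"p3d"` (default) reuses the null-model variance
#'   ratio for every SNP; `"exact"` re-estimates it per SNP by REML.
#' @return data.frame with one row per SNP: `locus`, `effect`, `se`,
#'   `stat`, `p`, `significant` (Bonferroni at `alpha` over the number
#'   of SNPs actually tested).  Attributes `lambda`, `sigmaG2`,
#'   `sigmaE2`, `m` and `threshold` describe the fit.
#' @export
mlmScan <- function(y, gm, K = NULL, pcs = NULL, nPcs = 0L,
                    alpha = 0.05, method = c("p3d", "exact")) {
    method <- match.arg(method)
    al <- .alignScan(y, gm, K, pcs)
    acc <- al$acc
    X0 <- cbind(Intercept = rep(1, length(acc)))
    if (!is.null(pcs) && nPcs > 0L)
        X0 <- cbind(X0, pcs[acc, seq_len(nPcs), drop = FALSE])
    G <- minorDosage(gm)[, acc, drop = FALSE] * 1.0
    n <- length(acc)
    if (!is.null(K)) {
        eig <- eigen(K[acc, acc], symmetric = TRUE)
        d <- pmax(eig$values, 0)
        U <- eig$vectors
        ys <- drop(crossprod(U, al$y))
        X0s <- crossprod(U, X0)
    } else {
        d <- rep(0, n); U <- NULL; ys <- al$y; X0s <- X0
    }
    null <- .mmFit(ys, X0s, d, reml = TRUE)
    lambda <- if (is.null(K)) 0 else null$lambda
    res <- data.frame(locus = rownames(gm), effect = NA_real_,
                      se = NA_real_, stat = NA_real_, p = NA_real_)
    w <- 1 / (lambda * d + 1)
    for (i in seq_len(nrow(G))) {
        x <- G[i, ]
        if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
        if (length(unique(x)) < 2L || anyNA(x)) next
        xs <- if (is.null(U)) x else drop(crossprod(U, x))
        Xs <- cbind(X0s, snp = xs)
        if (method == "exact" && !is.null(K)) {
            f <- .mmFit(ys, Xs, d, reml = TRUE)
            wi <- f$weights
        } else wi <- w
        fit <- lm.wfit(Xs, ys, wi)
        if (fit$rank < ncol(Xs)) next
        q <- ncol(Xs)
        rss <- sum(wi * fit$residuals^2)
        s2 <- rss / (n - q)
        XtWXinv <- chol2inv(chol(crossprod(Xs * sqrt(wi))))
        se <- sqrt(s2 * XtWXinv[q, q])
        beta <- fit$coefficients[["snp"]]
        tval <- beta / se
        res$effect[i] <- beta
        res$se[i] <- se
        res$stat[i] <- tval
        res$p[i] <- 2 * pt(-abs(tval), df = n - q)
    }
    m <- sum(!is.na(res$p))
    thr <- bonferroniThreshold(alpha, max(m, 1L))
    res$significant <- !is.na(res$p) & res$p < thr
    attr(res, "lambda") <- lambda
    attr(res, "sigmaG2") <- if (is.null(K)) 0 else null$sigmaG2
    attr(res, "sigmaE2") <- null$sigmaE2
    attr(res, "m") <- m
    attr(res, "threshold") <- thr
    res
}
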