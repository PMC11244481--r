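#' Centered cross-product kinship matrix
#'
#' VanRaden-type estimator \eqn{K = W W^T / c} with \eqn{W_{ij} =
#' x_{ij} - 2\hat p_j} (missing calls mean-imputed per SNP) and
#' normalizer \eqn{c = 2 \sum_j \hat p_j (1 - \hat p_j)}.  A small
#' ridge (1e-6) is added to the diagonal so the matrix is numerically
#' positive semidefinite.
#'
#' @param genotypes A \linkS4class{GenotypeData}.
#' @return Symmetric n x n matrix with the sample ordering of the input.
#' @export
computeKinship <- function(genotypes) {
    d <- dosage(genotypes)
    if (ncol(d) < 2L || nrow(d) < 2L) stop("need >= 2 samples and >= 2 SNPs")
    X <- .imputedSampleMatrix(d)           # samples x snps
    p <- colMeans(X) / 2
    c0 <- 2 * sum(p * (1 - p))
    if (c0 == 0) stop("all SNPs monomorphic: kinship undefined")
    W <- sweep(X, 2L, 2 * p)
    K <- tcrossprod(W) / c0
    K <- (K + t(K)) / 2
    diag(K) <- diag(K) + 1e-6
    dimnames(K) <- list(colnames(d), colnames(d))
    K
}

## snps x samples dosage -> samples x snps numeric, per-SNP mean imputation
.imputedSampleMatrix <- function(d) {
    X <- t(d) * 1.0
    if (anyNA(X)) {
        mu <- colMeans(X, na.rm = TRUE)
        idx <- which(is.na(X), arr.ind = TRUE)
        X[idx] <- mu[idx[, 2L]]
    }
    X
}

#' Principal-component structure covariates
#'
#' Top-\code{q} left singular vectors (scaled by singular values) of the
#' column-centered, mean-imputed genotype matrix.  Sign convention: each
#' component is flipped so its largest-magnitude SNP loading is
#' positive, making results deterministic across platforms.
#'
#' @param genotypes A \linkS4class{GenotypeData}.
#' @param q Number of components (0 gives an n x 0 matrix, making
#'   PCA-adjusted models collapse to their unadjusted versions).
#' @return n x q matrix of scores; columns are mean-zero and mutually
#'   orthogonal.
#' @export
computePCs <- function(genotypes, q = 3L) {
    d <- dosage(genotypes)
    n <- ncol(d)
    if (q >= n) stop("q must be < number of samples")
    ids <- colnames(d)
    if (q == 0L)
        return(matrix(numeric(0), n, 0, dimnames = list(ids, NULL)))
    X <- .imputedSampleMatrix(d)
    X <- sweep(X, 2L, colMeans(X))
    sv <- svd(X, nu = q, nv = q)
    sc <- sv$u %*% diag(sv$d[seq_len(q)], q, q)
    for (k in seq_len(q)) {
        j <- which.max(abs(sv$v[, k]))
        if (sv$v[j, k] < 0) sc[, k] <- -sc[, k]
    }
    dimnames(sc) <- list(ids, paste0("PC", seq_len(q)))
    sc
}

#' Greedy windowed LD pruning
#'
#' Within each non-overlapping (or sliding) window of \code{window}
#' SNPs per chromosome, pairs with squared dosage correlation at or
#' above \code{r2Max} are broken by removing the SNP with the lower
#' minor-allele frequency (tie: the later position), repeatedly until
#' no retained within-window pair violates the cutoff; the window then
#' slides by \code{step} SNPs.
#'
#' @param genotypes A \linkS4class{GenotypeData}.
#' @param window,step Window size and slide, in SNP counts.
#' @param r2Max Squared-correlation cutoff (pairs \eqn{r^2 \ge} cutoff
#'   are pruned).
#' @return Character vector of retained SNP ids, in genome order.
#' @export
ldPrune <- function(genotypes, window = 50L, step = 50L, r2Max = 0.2) {
    stopifnot(window >= step, step >= 1)
    info <- snpInfo(genotypes)
    d <- dosage(genotypes)
    maf <- pmin(rowMeans(d, na.rm = TRUE) / 2,
                1 - rowMeans(d, na.rm = TRUE) / 2)
    keep <- rep(TRUE, nrow(d))
    for (cc in unique(info$chrom)) {
        idx <- which(info$chrom == cc)
        starts <- seq(1L, length(idx), by = step)
        for (s in starts) {
            w <- idx[s:min(s + window - 1L, length(idx))]
            repeat {
                act <- w[keep[w]]
                if (length(act) < 2L) break
                r <- suppressWarnings(
                    cor(t(d[act, , drop = FALSE]),
                        use = "pairwise.complete.obs"))
                r2 <- r^2
                r2[is.na(r2)] <- 0
                diag(r2) <- 0
                if (max(r2) < r2Max) break
                ij <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
                a <- act[ij[1L]]; b <- act[ij[2L]]
                drop <- if (maf[a] < maf[b]) a
                        else if (maf[b] < maf[a]) b
                        else if (info$pos[a] > info$pos[b]) a else b
                keep[drop] <- FALSE
            }
        }
    }
    info$id[keep]
}

## residualize columns of M on design C (with intercept) via QR
.residualize <- function(M, C) {
    qrC <- qr(C)
    M - C %*% qr.coef(qrC, M)
}

#' Single-locus fixed-effects (GLM) association scan
#'
#' Per SNP, ordinary least squares of the trait on alt-allele dosage
#' plus optional structure covariates; the marker p-value is the 1-df
#' partial F-test and PVE its partial R-squared.  Samples with a
#' missing call at a SNP are dropped for that SNP (complete-case).
#' Monomorphic SNPs are reported with \eqn{\beta = 0}, \eqn{p = 1} and
#' a note.
#'
#' @param genotypes A \linkS4class{GenotypeData}.
#' @param trait Named numeric vector (e.g. BLUPs) covering the samples.
#' @param covariates Optional n x q numeric matrix (e.g.
#'   \code{\link{computePCs}} output), rows aligned to samples.
#' @param model Tag recorded in the result (\code{"GLM"},
#'   \code{"GLM_Q"}, \code{"GLM_PCA"}).
#' @return \code{data.frame}: \code{snp}, \code{chrom}, \code{pos},
#'   \code{model}, \code{beta}, \code{p}, \code{pve}, \code{note}.
#' @export
glmScan <- function(genotypes, trait, covariates = NULL, model = "GLM") {
    d <- dosage(genotypes)
    info <- snpInfo(genotypes)
    ids <- colnames(d)
    stopifnot(!is.null(names(trait)), all(ids %in% names(trait)))
    y <- as.numeric(trait[ids])
    n <- length(y)
    C <- cbind(rep(1, n), covariates)
    k <- ncol(C)
    out <- data.frame(snp = info$id, chrom = info$chrom, pos = info$pos,
                      model = model, beta = NA_real_, p = NA_real_,
                      pve = NA_real_, note = "", stringsAsFactors = FALSE)
    if (!anyNA(d)) {
        yr <- .residualize(y, C)
        Xr <- .residualize(t(d) * 1.0, C)
        sxx <- colSums(Xr^2)
        sxy <- as.numeric(crossprod(Xr, yr))
        syy <- sum(yr^2)
        mono <- sxx < 1e-12
        beta <- ifelse(mono, 0, sxy / sxx)
        ssm <- beta^2 * sxx
        df <- n - k - 1L
        rss <- pmax(syy - ssm, 0)
        Fst <- ifelse(mono, 0, ssm / (rss / df))
        out$beta <- beta
        out$p <- ifelse(mono, 1, pf(Fst, 1, df, lower.tail = FALSE))
        out$pve <- ifelse(mono, 0, pmin(ssm / syy, 1))
        out$note <- ifelse(mono, "monomorphic", "")
        return(out)
    }
    for (j in seq_len(nrow(d))) {
        x <- d[j, ] * 1.0
        cc <- !is.na(x) & !is.na(y)
        xj <- x[cc]; yj <- y[cc]; Cj <- C[cc, , drop = FALSE]
        if (length(unique(xj)) < 2L || sum(cc) <= k + 1L) {
            out$beta[j] <- 0; out$p[j] <- 1; out$pve[j] <- 0
            out$note[j] <- "monomorphic"
            next
        }
        yr <- .residualize(yj, Cj)
        xr <- .residualize(xj, Cj)
        sxx <- sum(xr^2); sxy <- sum(xr * yr); syy <- sum(yr^2)
        beta <- sxy / sxx
        ssm <- beta^2 * sxx
        df <- sum(cc) - k - 1L
        out$beta[j] <- beta
        out$p[j] <- pf(ssm / ((syy - ssm) / df), 1, df, lower.tail = FALSE)
        out$pve[j] <- min(ssm / syy, 1)
    }
    out
}

## REML of the null mixed model y = Xb + u + e, Var(u) = s2g*K, on the
## spectral decomposition of K.  Returns delta = s2e/s2g, s2g, s2e and
## the rotation.
.nullREML <- function(y, C, K) {
    n <- length(y)
    ek <- eigen(K, symmetric = TRUE)
    lam <- pmax(ek$values, 0)
    U <- ek$vectors
    ys <- crossprod(U, y)
    Cs <- crossprod(U, C)
    q <- ncol(C)
    ldXX <- determinant(crossprod(C), logarithm = TRUE)$modulus
    negREML <- function(logDelta) {
        delta <- exp(logDelta)
        w <- 1 / (lam + delta)
        XtWX <- crossprod(Cs, Cs * w)
        XtWy <- crossprod(Cs, ys * w)
        bh <- solve(XtWX, XtWy)
        r <- ys - Cs %*% bh
        rss <- sum(w * r^2)
        s2 <- rss / (n - q)
        0.5 * ((n - q) * log(2 * pi * s2) + sum(log(lam + delta)) +
               determinant(XtWX, logarithm = TRUE)$modulus - ldXX +
               (n - q))
    }
    ## coarse grid then local refinement, bracketing delta in 10^[-6, 6]
    grid <- seq(log(1e-6), log(1e6), length.out = 61L)
    vals <- vapply(grid, negREML, numeric(1))
    i0 <- which.min(vals)
    lo <- grid[max(1L, i0 - 1L)]; hi <- grid[min(length(grid), i0 + 1L)]
    opt <- optimize(negREML, c(lo, hi))
    delta <- exp(opt$minimum)
    w <- 1 / (lam + delta)
    XtWX <- crossprod(Cs, Cs * w)
    bh <- solve(XtWX, crossprod(Cs, ys * w))
    r <- ys - Cs %*% bh
    s2g <- sum(w * r^2) / (n - q)
    list(delta = delta, s2g = s2g, s2e = delta * s2g, U = U, lam = lam,
         ys = as.numeric(ys), Cs = Cs)
}

#' Single-locus mixed-model (MLM) association scan
#'
#' EMMA-style mixed model \eqn{y = X\beta + z b + u + e}, \eqn{u \sim
#' N(0, \sigma^2_g K)}.  Variance components are estimated once on the
#' null model by REML over the spectral decomposition of K
#' (population-parameters-previously-determined); each marker is then
#' tested by 1-df generalized least squares with an F reference
#' (\eqn{t^2} with \eqn{n - q - 1} denominator df), which collapses
#' exactly to the GLM F-test as \eqn{\sigma^2_g \to 0}.  PVE is the
#' partial R-squared on the whitened scale.
#'
#' @inheritParams glmScan
#' @param kinship Kinship matrix from \code{\link{computeKinship}},
#'   sample-aligned.
#' @param model Tag recorded in the result (\code{"MLM_K"},
#'   \code{"MLM_QK"}, \code{"MLM_PCAK"}).
#' @return \code{data.frame} with the \code{\link{glmScan}} schema.
#' @export
mlmScan <- function(genotypes, trait, kinship, covariates = NULL,
                    model = "MLM_K") {
    d <- dosage(genotypes)
    info <- snpInfo(genotypes)
    ids <- colnames(d)
    stopifnot(all(ids %in% names(trait)),
              all(ids %in% rownames(kinship)))
    y <- as.numeric(trait[ids])
    K <- kinship[ids, ids]
    n <- length(y)
    C <- cbind(rep(1, n), covariates)
    q <- ncol(C)
    nm <- .nullREML(y, C, K)
    w <- 1 / (nm$lam + nm$delta)
    sw <- sqrt(w)
    yt <- sw * nm$ys
    Ct <- sw * nm$Cs
    X <- .imputedSampleMatrix(d)                  # samples x snps
    Xt <- sw * crossprod(nm$U, X)                 # whitened markers
    yr <- .residualize(yt, Ct)
    Xr <- .residualize(Xt, Ct)
    sxx <- colSums(Xr^2)
    sxy <- as.numeric(crossprod(Xr, yr))
    syy <- sum(yr^2)
    mono <- sxx < 1e-12
    beta <- ifelse(mono, 0, sxy / sxx)
    ssm <- beta^2 * sxx
    df <- n - q - 1L
    rss <- pmax(syy - ssm, 0)
    Fst <- ifelse(mono, 0, ssm / (rss / df))
    data.frame(snp = info$id, chrom = info$chrom, pos = info$pos,
               model = model, beta = beta,
               p = ifelse(mono, 1, pf(Fst, 1, df, lower.tail = FALSE)),
               pve = ifelse(mono, 0, pmin(ssm / syy, 1)),
               note = ifelse(mono, "monomorphic", ""),
               stringsAsFactors = FALSE)
}

#' Run all six single-locus association models
#'
#' Convenience wrapper producing one result table with model tags GLM,
#' GLM_Q, GLM_PCA, MLM_K, MLM_QK, MLM_PCAK.  The Q-style covariates are
#' principal components as well (a standard surrogate for
#' STRUCTURE-derived ancestry fractions); \code{qQ} and \code{qPCA}
#' control how many components each variant uses.
#'
#' @inheritParams mlmScan
#' @param qQ,qPCA Number of PCs used for the Q-style and PCA-style
#'   covariates.
#' @return \code{data.frame}, six rows per SNP (one per model tag).
#' @export
scanAllSingleLocus <- function(genotypes, trait, kinship = NULL,
                               qQ = 2L, qPCA = 3L) {
    if (is.null(kinship)) kinship <- computeKinship(genotypes)
    pcQ <- computePCs(genotypes, qQ)
    pcP <- computePCs(genotypes, qPCA)
    rbind(glmScan(genotypes, trait, NULL, "GLM"),
          glmScan(genotypes, trait, pcQ, "GLM_Q"),
          glmScan(genotypes, trait, pcP, "GLM_PCA"),
          mlmScan(genotypes, trait, kinship, NULL, "MLM_K"),
          mlmScan(genotypes, trait, kinship, pcQ, "MLM_QK"),
          mlmScan(genotypes, trait, kinship, pcP, "MLM_PCAK"))
}

#' Bonferroni genome-wide significance threshold
#'
#' @param nTests Number of markers tested.
#' @param fwer Family-wise error rate (default 0.01: with 39,327
#'   markers this reproduces the conventional 2.54e-7 threshold,
#'   -log10 p = 6.59).
#' @return List with \code{p} (= \code{fwer / nTests}) and
#'   \code{negLog10}.
#' @export
bonferroniThreshold <- function(nTests, fwer = 0.01) {
    stopifnot(nTests >= 1, fwer > 0, fwer < 1)
    p <- fwer / nTests
    list(p = p, negLog10 = -log10(p))
}

#' Genomic-control inflation factor
#'
#' \eqn{\lambda_{GC}} = median of the 1-df chi-square statistics implied
#' by the p-values, divided by the null median 0.4549.
#'
#' @param p Vector of p-values.
#' @return Numeric scalar.
#' @export
genomicInflation <- function(p) {
    p <- p[!is.na(p)]
    chi <- qchisq(p, df = 1, lower.tail = FALSE)
    median(chi) / qchisq(0.5, df = 1)
}

#' Manhattan and QQ plots of an association scan
#'
#' Writes a single PNG with a per-chromosome colored Manhattan panel
#' (with the significance threshold line) and a QQ panel of observed
#' vs expected -log10 p.
#'
#' @param results Result table from \code{\link{glmScan}} /
#'   \code{\link{mlmScan}} (one model).
#' @param threshold P-value drawn as the genome-wide line.
#' @param path Output PNG path.
#' @return Invisibly, the plotted coordinates (\code{neglog}, expected
#'   quantiles, threshold line height).
#' @importFrom grDevices png dev.off
#' @importFrom graphics abline axis par points plot
#' @export
manhattanQQPlot <- function(results, threshold, path) {
    if (nrow(results) == 0L) stop("empty result table")
    res <- results[order(results$chrom, results$pos), ]
    nl <- -log10(pmax(res$p, .Machine$double.xmin))
    chr <- factor(res$chrom, levels = unique(res$chrom))
    xoff <- c(0, cumsum(tapply(res$pos, chr, max)))
    x <- res$pos + xoff[as.integer(chr)]
    m <- nrow(res)
    expq <- -log10((seq_len(m) - 0.5) / m)
    obs <- sort(nl, decreasing = TRUE)
    grDevices::png(path, width = 1400, height = 600)
    op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    plot(x, nl, col = (as.integer(chr) %% 2) + 1, pch = 20,
         xlab = "position", ylab = "-log10(p)",
         main = unique(res$model)[1L], xaxt = "n")
    mid <- tapply(x, chr, mean)
    axis(1, at = mid, labels = levels(chr), las = 2, cex.axis = 0.7)
    abline(h = -log10(threshold), col = "red", lty = 2)
    plot(expq, obs, pch = 20, xlab = "expected -log10(p)",
         ylab = "observed -log10(p)", main = "QQ")
    abline(0, 1, col = "red")
    par(op)
    grDevices::dev.off()
    invisible(list(neglog = nl, expected = expq, observed = obs,
                   thresholdLine = -log10(threshold)))
}
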