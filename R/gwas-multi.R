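#' Two-stage multi-locus association scan with LOD scoring
#'
#' A representative of the multi-locus random-SNP-effect model family.
#' Stage 1 runs the single-marker mixed-model scan
#' (\code{\link{mlmScan}}) and retains markers with \eqn{p \le}
#' \code{stage1P}.  Stage 2 fits, on the whitened (mixed-model
#' decorrelated) scale, the joint model \eqn{y = X\beta + \sum_k z_k
#' b_k + e} with zero-mean Gaussian marker effects whose
#' marker-specific variances are estimated by expectation-maximization
#' empirical Bayes (automatic-relevance-determination shrinkage;
#' iteration cap 1000, relative tolerance 1e-8, variance floor 1e-10).
#' Markers whose prior variance survives shrinkage enter a final joint
#' fit; each gets \eqn{LOD_k = n \ln(RSS_{-k} / RSS) / (2 \ln 10)}, the
#' likelihood-ratio statistic converted to base-10 units, and markers
#' with LOD at or above \code{lodMin} are reported.
#'
#' @param genotypes A \linkS4class{GenotypeData}.
#' @param trait Named numeric trait vector (BLUPs).
#' @param kinship Kinship matrix; computed from the genotypes when
#'   \code{NULL}.
#' @param stage1P Stage-1 retention p-value threshold.
#' @param lodMin LOD threshold for reported markers.
#' @return \code{data.frame}: \code{snp}, \code{chrom}, \code{pos},
#'   \code{stage1P}, \code{effect} (empirical-Bayes posterior mean),
#'   \code{lod}, \code{pve}; only markers with \code{lod >= lodMin}.
#' @export
multilocusScan <- function(genotypes, trait, kinship = NULL,
                           stage1P = 0.01, lodMin = 3.0) {
    if (is.null(kinship)) kinship <- computeKinship(genotypes)
    s1 <- mlmScan(genotypes, trait, kinship, NULL, model = "stage1")
    empty <- data.frame(snp = character(0), chrom = character(0),
                        pos = integer(0), stage1P = numeric(0),
                        effect = numeric(0), lod = numeric(0),
                        pve = numeric(0), stringsAsFactors = FALSE)
    sel <- which(s1$p <= stage1P & s1$note == "")
    if (length(sel) == 0L) {
        message("stage 1 retained no markers")
        return(empty)
    }
    d <- dosage(genotypes)
    n <- ncol(d)
    if (length(sel) > n / 2) {
        warning("stage 1 retained > n/2 markers; keeping top n/2 by p")
        sel <- sel[order(s1$p[sel])][seq_len(floor(n / 2))]
        sel <- sort(sel)
    }
    ids <- colnames(d)
    y <- as.numeric(trait[ids])
    K <- kinship[ids, ids]
    C <- matrix(1, n, 1)
    nm <- .nullREML(y, C, K)
    sw <- sqrt(1 / (nm$lam + nm$delta))
    yt <- sw * nm$ys
    Ct <- sw * nm$Cs
    X <- .imputedSampleMatrix(d)[, sel, drop = FALSE]
    Zt <- sw * crossprod(nm$U, X)
    yr <- as.numeric(.residualize(yt, Ct))
    Zr <- .residualize(Zt, Ct)
    eb <- .emBayesRidge(yr, Zr)
    keep <- which(eb$s2k > 1e-8 * var(yr) & abs(eb$mu) > 0)
    if (length(keep) == 0L) return(empty)
    ## final joint fit and per-marker likelihood-ratio LOD
    Zf <- Zr[, keep, drop = FALSE]
    fitRSS <- function(M) {
        if (ncol(M) == 0L) return(sum(yr^2))
        sum(qr.resid(qr(M), yr)^2)
    }
    rssFull <- fitRSS(Zf)
    lod <- vapply(seq_along(keep), function(j) {
        rss0 <- fitRSS(Zf[, -j, drop = FALSE])
        max(0, n * log(rss0 / rssFull) / (2 * log(10)))
    }, numeric(1))
    vz <- apply(Zf, 2L, var)
    pve <- pmin(eb$mu[keep]^2 * vz / var(yr), 1)
    res <- data.frame(snp = s1$snp[sel][keep],
                      chrom = s1$chrom[sel][keep],
                      pos = s1$pos[sel][keep],
                      stage1P = s1$p[sel][keep],
                      effect = eb$mu[keep], lod = lod, pve = pve,
                      stringsAsFactors = FALSE)
    res[res$lod >= lodMin, , drop = FALSE]
}

## EM empirical Bayes for y = Z b + e with b_k ~ N(0, s2k), e ~ N(0, s2)
.emBayesRidge <- function(y, Z, maxIter = 1000L, tol = 1e-8,
                          floor = 1e-10) {
    n <- length(y)
    m <- ncol(Z)
    ZtZ <- crossprod(Z)
    Zty <- as.numeric(crossprod(Z, y))
    s2k <- rep(var(y) / max(m, 1), m)
    s2 <- var(y)
    mu <- rep(0, m)
    for (it in seq_len(maxIter)) {
        A <- ZtZ / s2
        diag(A) <- diag(A) + 1 / s2k
        Sig <- solve(A)
        muNew <- as.numeric(Sig %*% Zty) / s2
        s2kNew <- pmax(muNew^2 + diag(Sig), floor)
        r <- y - Z %*% muNew
        s2New <- max(as.numeric(crossprod(r)) +
                     sum(ZtZ * Sig), floor * n) / n
        rel <- max(abs(c(s2kNew - s2k, s2New - s2))) /
            max(abs(c(s2k, s2)), 1e-30)
        mu <- muNew; s2k <- s2kNew; s2 <- s2New
        if (rel < tol) break
    }
    ## hard shrinkage: variances driven to (near) the floor are zeroed
    dead <- s2k <= floor * 10
    mu[dead] <- 0
    s2k[dead] <- 0
    list(mu = mu, s2k = s2k, s2 = s2, iter = it)
}

#' Merge significant markers into loci by single-linkage chaining
#'
#' Markers on the same chromosome are sorted by position; consecutive
#' markers at most \code{maxGap} bp apart join one locus (so a locus is
#' a chain whose adjacent gaps never exceed the cutoff).  Each locus is
#' represented by its best-scoring member.
#'
#' @param hits \code{data.frame} with \code{snp}, \code{chrom},
#'   \code{pos} and a score column: \code{lod} (higher is better) or
#'   \code{p} (lower is better); \code{lod} wins if both are present.
#' @param maxGap Maximum within-locus gap in bp (default 20 kb).
#' @return \code{data.frame}: \code{chrom}, \code{pos} (representative),
#'   \code{snp} (representative id), \code{members}
#'   (comma-separated ids), \code{n}, \code{best} (score of the
#'   representative).
#' @export
mergeLoci <- function(hits, maxGap = 20000L) {
    stopifnot(all(c("chrom", "pos") %in% names(hits)))
    out <- list()
    if (nrow(hits) == 0L)
        return(data.frame(chrom = character(0), pos = integer(0),
                          snp = character(0), members = character(0),
                          n = integer(0), best = numeric(0),
                          stringsAsFactors = FALSE))
    useLod <- "lod" %in% names(hits)
    score <- if (useLod) hits$lod else if ("p" %in% names(hits))
        -log10(hits$p) else rep(0, nrow(hits))
    if (!"snp" %in% names(hits))
        hits$snp <- paste0(hits$chrom, "_", hits$pos)
    for (cc in sort(unique(hits$chrom))) {
        idx <- which(hits$chrom == cc)
        idx <- idx[order(hits$pos[idx])]
        grp <- cumsum(c(1L, diff(hits$pos[idx]) > maxGap))
        for (g in unique(grp)) {
            mem <- idx[grp == g]
            rep_ <- mem[which.max(score[mem])]
            out[[length(out) + 1L]] <- data.frame(
                chrom = cc, pos = hits$pos[rep_], snp = hits$snp[rep_],
                members = paste(hits$snp[mem], collapse = ","),
                n = length(mem),
                best = if (useLod) hits$lod[rep_]
                       else if ("p" %in% names(hits)) hits$p[rep_]
                       else NA_real_,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}
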