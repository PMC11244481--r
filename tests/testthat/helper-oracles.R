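# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately brute-force / closed-form and never
# calls the package functions it is used to check.

# build a GenotypeData from a dosage matrix laid out samples x snps
toyGenotypes <- function(d, chrom = NULL, pos = NULL) {
    m <- ncol(d)
    if (is.null(chrom)) chrom <- rep("chr1", m)
    if (is.null(pos)) pos <- seq_len(m) * 1000L
    dm <- t(d)
    rownames(dm) <- sprintf("s%03d", seq_len(m))
    colnames(dm) <- if (is.null(rownames(d)))
        sprintf("S%02d", seq_len(nrow(d))) else rownames(d)
    GenotypeData(dm, chrom = chrom, pos = pos,
                 ref = rep("A", m), alt = rep("G", m))
}

# REML of y = mu + u_sample + u_rep + e by dense grid search over the
# two variance ratios, with sigma2_e profiled out
blupOracle <- function(traits, gridN = 81L) {
    y <- traits$content
    n <- length(y)
    Z1 <- outer(traits$sample, unique(traits$sample), "==") * 1.0
    Z2 <- outer(traits$rep, unique(traits$rep), "==") * 1.0
    X <- matrix(1, n, 1)
    p <- 1L
    crit <- function(g1, g2) {
        V0 <- diag(n) + g1 * tcrossprod(Z1) + g2 * tcrossprod(Z2)
        Vi <- solve(V0)
        XtViX <- crossprod(X, Vi %*% X)
        bh <- solve(XtViX, crossprod(X, Vi %*% y))
        r <- y - X %*% bh
        s2 <- as.numeric(crossprod(r, Vi %*% r)) / (n - p)
        0.5 * ((n - p) * log(s2) +
               determinant(V0, logarithm = TRUE)$modulus +
               determinant(XtViX, logarithm = TRUE)$modulus)
    }
    g <- c(0, 10^seq(-4, 4, length.out = gridN))
    best <- c(0, 0); bc <- Inf
    for (a in g) for (b in g) {
        v <- crit(a, b)
        if (v < bc) { bc <- v; best <- c(a, b) }
    }
    # local refinement around the coarse optimum, shrinking the span
    span <- 0.2
    for (rep in 1:6) {
        ga <- best[1] * 10^seq(-span, span, length.out = 25L)
        gb <- best[2] * 10^seq(-span, span, length.out = 25L)
        if (best[1] == 0) ga <- c(0, 10^seq(-8, -4, length.out = 10L))
        if (best[2] == 0) gb <- c(0, 10^seq(-8, -4, length.out = 10L))
        for (a in ga) for (b in gb) {
            v <- crit(a, b)
            if (v < bc) { bc <- v; best <- c(a, b) }
        }
        span <- span * 0.35
    }
    g1 <- best[1]; g2 <- best[2]
    V0 <- diag(n) + g1 * tcrossprod(Z1) + g2 * tcrossprod(Z2)
    Vi <- solve(V0)
    bh <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y))
    r <- y - X %*% bh
    s2e <- as.numeric(crossprod(r, Vi %*% r)) / (n - p)
    u <- g1 * crossprod(Z1, Vi %*% r)
    list(mu = as.numeric(bh),
         blup = setNames(as.numeric(bh) + as.numeric(u),
                         unique(traits$sample)),
         varcomp = c(sample = g1 * s2e, rep = g2 * s2e, residual = s2e))
}

# grid-search REML + GLS oracle for the single-marker mixed model
mlmOracle <- function(y, x, K) {
    n <- length(y)
    X0 <- matrix(1, n, 1)
    crit <- function(delta) {
        V0 <- K + delta * diag(n)
        Vi <- solve(V0)
        XtViX <- crossprod(X0, Vi %*% X0)
        bh <- solve(XtViX, crossprod(X0, Vi %*% y))
        r <- y - X0 %*% bh
        s2 <- as.numeric(crossprod(r, Vi %*% r)) / (n - 1)
        0.5 * ((n - 1) * log(s2) +
               determinant(V0, logarithm = TRUE)$modulus +
               determinant(XtViX, logarithm = TRUE)$modulus)
    }
    ld <- seq(-6, 6, by = 0.01)
    vals <- vapply(10^ld, crit, numeric(1))
    delta <- 10^ld[which.min(vals)]
    o <- optimize(function(l) crit(exp(l)),
                  log(delta) + c(-0.1, 0.1))
    delta <- exp(o$minimum)
    V0 <- K + delta * diag(n)
    Vi <- solve(V0)
    A <- cbind(1, x)
    bh <- solve(crossprod(A, Vi %*% A), crossprod(A, Vi %*% y))
    r <- y - A %*% bh
    df <- n - 2L
    s2 <- as.numeric(crossprod(r, Vi %*% r)) / df
    se <- sqrt(s2 * solve(crossprod(A, Vi %*% A))[2, 2])
    tt <- bh[2] / se
    list(delta = delta, beta = as.numeric(bh[2]),
         p = stats::pf(tt^2, 1, df, lower.tail = FALSE))
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
    tab <- table(a, b)
    ch2 <- function(x) x * (x - 1) / 2
    sij <- sum(ch2(tab))
    si <- sum(ch2(rowSums(tab)))
    sj <- sum(ch2(colSums(tab)))
    nt <- ch2(sum(tab))
    exp0 <- si * sj / nt
    (sij - exp0) / ((si + sj) / 2 - exp0)
}

# brute-force ORF scan over every ATG / in-frame stop pair
orfOracle <- function(s, minLen = 150L) {
    s <- toupper(s)
    n <- nchar(s)
    best <- NULL
    for (st in seq_len(n - 2L)) {
        if (substr(s, st, st + 2L) != "ATG") next
        en <- st + 3L
        while (en + 2L <= n) {
            cod <- substr(s, en, en + 2L)
            if (cod %in% c("TAA", "TAG", "TGA")) {
                len <- en + 2L - st + 1L
                if (len >= minLen &&
                    (is.null(best) || len > best$length ||
                     (len == best$length && st < best$start)))
                    best <- list(start = st, end = en + 2L, length = len)
                break
            }
            en <- en + 3L
        }
    }
    best
}

# triple-loop TOM evaluation
tomOracle <- function(a) {
    m <- nrow(a)
    diag(a) <- 0
    k <- rowSums(a)
    tom <- diag(m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
        if (i == j) next
        l <- 0
        for (u in seq_len(m)) if (u != i && u != j)
            l <- l + a[i, u] * a[u, j]
        tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    tom
}

# write a small VCF given genotype strings (rows = variants)
writeToyVCF <- function(path, rows,
                        samples = c("S1", "S2", "S3")) {
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", samples),
                       collapse = "\t"),
                 rows), path)
    path
}
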