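test_that("kinship equals the centered cross-product formula", {
    d <- matrix(c(0, 1, 2, 0,
                  1, 1, 0, 2,
                  2, 0, 1, 1), nrow = 3, byrow = TRUE)  # samples x snps
    gt <- toyGenotypes(d)
    K <- computeKinship(gt)
    p <- colMeans(d) / 2
    W <- sweep(d, 2, 2 * p)
    Kexp <- tcrossprod(W) / (2 * sum(p * (1 - p)))
    diag(Kexp) <- diag(Kexp) + 1e-6
    expect_equal(unname(K), unname(Kexp), tolerance = 1e-12)

    # identical genotype rows give identical kinship entries
    d2 <- rbind(d[1, ], d[1, ], d[3, ])
    K2 <- computeKinship(toyGenotypes(d2))
    # diagonal carries the 1e-6 stabilization ridge
    expect_equal(K2[1, 2] + 1e-6, K2[1, 1], tolerance = 1e-12)
    expect_equal(K2[1, 2] + 1e-6, K2[2, 2], tolerance = 1e-12)
})

test_that("kinship is symmetric and PSD on random fixtures", {
    for (s in 1:50) {
        set.seed(s)
        d <- matrix(sample(0:2, 8 * 12, replace = TRUE), 8, 12)
        K <- computeKinship(toyGenotypes(d))
        expect_true(isSymmetric(K))
        expect_gte(min(eigen(K, symmetric = TRUE,
                             only.values = TRUE)$values), -1e-10)
    }
})

test_that("principal components separate planted subpopulations", {
    cfg <- simConfig(nSamples = 100, nSnps = 400, nChrom = 4,
                     nSubpops = 2, fst = 0.3, ldRho = 0, seed = 6)
    gt <- simulateGenotypes(cfg)
    pc <- computePCs(gt, 3)
    sub <- SummarizedExperiment::colData(gt)$subpop
    expect_gt(abs(cor(pc[, 1], sub)), 0.9)
    # orthogonality
    g <- crossprod(pc)
    expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
    # q = 0 covariates make GLM_PCA collapse to GLM
    bl <- setNames(rnorm(100), colnames(dosage(gt)))
    r0 <- glmScan(gt, bl, computePCs(gt, 0), "GLM_PCA")
    r1 <- glmScan(gt, bl, NULL, "GLM")
    expect_equal(r0$p, r1$p, tolerance = 1e-12)
    expect_error(computePCs(gt, 100), "q must be")
})

test_that("LD pruning removes duplicates and respects the r2 bound", {
    set.seed(13)
    d <- matrix(sample(0:2, 30 * 10, replace = TRUE), 30, 10)
    d[, 5] <- d[, 4]                       # exact duplicate pair
    gt <- toyGenotypes(d)
    kept <- ldPrune(gt, window = 10, step = 10, r2Max = 0.2)
    ids <- snpInfo(gt)$id
    expect_equal(sum(ids[c(4, 5)] %in% kept), 1L)
    # brute-force postcondition on the retained set
    ki <- match(kept, ids)
    r2 <- cor(d[, ki])^2
    expect_lt(max(r2[upper.tri(r2)]), 0.2)
})

test_that("independent SNPs survive pruning almost entirely", {
    frac <- vapply(1:20, function(s) {
        cfg <- simConfig(nSamples = 150, nSnps = 100, nChrom = 1,
                         ldRho = 0, nSubpops = 1, fst = 0, seed = s)
        gt <- simulateGenotypes(cfg)
        length(ldPrune(gt)) / 100
    }, numeric(1))
    expect_gte(mean(frac), 0.95)
})

test_that("GLM scan equals a normal-equations OLS oracle", {
    # printed 12-sample fixture
    x <- c(0, 1, 2, 0, 1, 2, 0, 0, 1, 2, 2, 1)
    cov1 <- c(0.3, -0.1, 0.2, 0.5, -0.4, 0.0, 0.1, -0.2, 0.3, 0.2,
              -0.5, 0.4)
    y <- c(0.62, 0.70, 0.91, 0.58, 0.73, 0.95, 0.55, 0.60, 0.74, 0.99,
           0.88, 0.71)
    gt <- toyGenotypes(matrix(x, ncol = 1))
    names(y) <- colnames(dosage(gt))
    res <- glmScan(gt, y, covariates = matrix(cov1, ncol = 1))
    # independent oracle: explicit normal equations
    X <- cbind(1, cov1, x)
    bh <- solve(crossprod(X), crossprod(X, y))
    r <- y - X %*% bh
    df <- 12 - 3
    s2 <- sum(r^2) / df
    se <- sqrt(s2 * solve(crossprod(X))[3, 3])
    Fo <- (bh[3] / se)^2
    expect_equal(res$beta, unname(bh[3]), tolerance = 1e-10)
    expect_equal(res$p, pf(Fo, 1, df, lower.tail = FALSE),
                 tolerance = 1e-10)
    # perfect fit: p underflows, PVE -> 1
    y2 <- setNames(0.1 * x, names(y))
    res2 <- glmScan(gt, y2)
    expect_lt(res2$p, 1e-15)
    expect_gt(res2$pve, 1 - 1e-10)
})

test_that("GLM p-values are uniform under permutation of the trait", {
    cfg <- simConfig(nSamples = 100, nSnps = 500, nChrom = 2, ldRho = 0,
                     nSubpops = 1, fst = 0, seed = 17)
    gt <- simulateGenotypes(cfg)
    set.seed(99)
    y <- setNames(rnorm(100), colnames(dosage(gt)))  # trait unrelated
    p <- glmScan(gt, y)$p
    expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.05)
})

test_that("MLM equals GLM when the kinship is the identity", {
    set.seed(3)
    d <- matrix(sample(0:2, 60 * 40, replace = TRUE), 60, 40)
    gt <- toyGenotypes(d)
    ids <- colnames(dosage(gt))
    y <- setNames(rnorm(60), ids)
    K <- diag(60); dimnames(K) <- list(ids, ids)
    pm <- mlmScan(gt, y, K)$p
    pg <- glmScan(gt, y)$p
    expect_lt(max(abs(pm - pg)), 1e-6)
})

test_that("MLM matches a grid-search REML GLS oracle on 8 samples", {
    set.seed(8)
    n <- 8
    d <- matrix(sample(0:2, n * 5, replace = TRUE), n, 5)
    gt <- toyGenotypes(d)
    ids <- colnames(dosage(gt))
    L <- matrix(rnorm(n * n), n)
    K <- tcrossprod(L) / n + diag(n) * 0.1
    dimnames(K) <- list(ids, ids)
    y <- setNames(as.numeric(L %*% rnorm(n)) * 0.3 + rnorm(n), ids)
    res <- mlmScan(gt, y, K)
    for (j in 1:5) {
        orc <- mlmOracle(unname(y), d[, j], K)
        expect_equal(res$beta[j], orc$beta, tolerance = 1e-4)
        expect_equal(res$p[j], orc$p, tolerance = 1e-4)
    }
})

test_that("kinship correction controls structure-driven inflation", {
    pG <- pM <- c()
    for (s in 1:20) {
        cfg <- simConfig(nSamples = 120, nSnps = 400, nChrom = 4,
                         nSubpops = 2, fst = 0.1, ldRho = 0.3,
                         seed = 100 + s)
        gt <- simulateGenotypes(cfg)
        ids <- colnames(dosage(gt))
        sub <- SummarizedExperiment::colData(gt)$subpop
        set.seed(200 + s)
        y <- setNames(0.5 * (sub - mean(sub)) + rnorm(120, 0, 0.5), ids)
        K <- computeKinship(gt)
        pG <- c(pG, glmScan(gt, y)$p)
        pM <- c(pM, mlmScan(gt, y, K)$p)
    }
    expect_gt(genomicInflation(pG), 1.2)
    lam <- genomicInflation(pM)
    expect_true(lam >= 0.9 && lam <= 1.1)
})

test_that("Bonferroni threshold reproduces the conventional constants", {
    b <- bonferroniThreshold(39327, 0.01)
    expect_equal(signif(b$p, 3), 2.54e-7)
    expect_equal(round(b$negLog10, 2), 6.59)
    expect_equal(bonferroniThreshold(1, 0.05)$p, 0.05)
    expect_equal(round(bonferroniThreshold(1, 0.05)$negLog10, 3), 1.301)
    expect_equal(bonferroniThreshold(100, 0.05)$p, 5e-4)
    expect_equal(round(bonferroniThreshold(100, 0.05)$negLog10, 3), 3.301)
})

test_that("Manhattan/QQ plot writes a file and passes the threshold through", {
    set.seed(7)
    res <- data.frame(snp = paste0("s", 1:100), chrom = "chr1",
                      pos = 1:100 * 1000, model = "GLM", beta = 0,
                      p = runif(100), pve = 0, note = "")
    f <- withr::local_tempfile(fileext = ".png")
    out <- manhattanQQPlot(res, 2.54e-7, f)
    expect_true(file.exists(f) && file.size(f) > 0)
    expect_equal(out$thresholdLine, -log10(2.54e-7))
    # QQ points inside the 95% order-statistic band for >= 90 of 100
    m <- 100
    i <- 1:m
    lo <- -log10(qbeta(0.975, i, m - i + 1))
    hi <- -log10(qbeta(0.025, i, m - i + 1))
    inside <- out$observed >= lo & out$observed <= hi
    expect_gte(sum(inside), 90)
    expect_error(manhattanQQPlot(res[0, ], 1e-5, f), "empty")
})

test_that("all six model tags share one result schema", {
    cfg <- simConfig(nSamples = 60, nSnps = 80, nChrom = 2, seed = 12)
    gt <- simulateGenotypes(cfg)
    tr <- simulateTrait(gt, cfg)
    bl <- blup(fitBlup(tr$traits))
    res <- scanAllSingleLocus(gt, bl)
    expect_equal(sort(unique(res$model)),
                 sort(c("GLM", "GLM_Q", "GLM_PCA", "MLM_K", "MLM_QK",
                        "MLM_PCAK")))
    expect_equal(nrow(res), 6L * 80L)
    expect_true(all(res$p > 0 & res$p <= 1))
    expect_true(all(res$pve >= 0 & res$pve <= 1))
})
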