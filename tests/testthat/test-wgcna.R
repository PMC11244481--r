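test_that("zero-expression filter applies a strict 70% rule", {
    n <- 344
    mk <- function(nzero) c(rep(0, nzero), runif(n - nzero, 1, 2))
    set.seed(1)
    expr <- rbind(over = mk(241),    # 70.06% zeros: removed
                  atPct = mk(240),   # 69.77%: kept
                  clean = mk(0))
    colnames(expr) <- paste0("S", 1:n)
    kept <- filterExpression(expr, 0.70)
    expect_false("over" %in% rownames(kept))
    expect_true(all(c("atPct", "clean") %in% rownames(kept)))

    # exactly at the threshold is retained (strict >)
    e10 <- rbind(a = c(rep(0, 7), 1, 1, 1), b = runif(10))
    colnames(e10) <- paste0("S", 1:10)
    expect_true("a" %in% rownames(filterExpression(e10, 0.70)))
    expect_error(filterExpression(rbind(z = rep(0, 10)), 0.5), "all genes")
})

test_that("the filter reproduces a 541-to-410 style narrowing", {
    # fixture constructed so 131 of 541 genes exceed the zero rule
    set.seed(7)
    n <- 344
    good <- matrix(runif(410 * n, 0.5, 3), 410, n)
    bad <- matrix(runif(131 * n, 0.5, 3), 131, n)
    for (i in 1:131) bad[i, sample.int(n, 250)] <- 0   # 72.7% zeros
    expr <- rbind(good, bad)
    rownames(expr) <- sprintf("g%03d", 1:541)
    colnames(expr) <- paste0("S", 1:n)
    expect_equal(nrow(filterExpression(expr, 0.70)), 410L)
})

test_that("outlier sample removal flags only planted outliers", {
    drops <- vapply(1:20, function(s) {
        set.seed(s)
        e <- matrix(rnorm(60 * 30), 60, 30,
                    dimnames = list(NULL, paste0("S", 1:30)))
        length(removeOutlierSamples(e)$dropped)
    }, numeric(1))
    expect_gte(sum(drops == 0), 18)

    set.seed(5)
    e <- matrix(rnorm(60 * 30), 60, 30,
                dimnames = list(NULL, paste0("S", 1:30)))
    e[, 7] <- e[, 7] + 10                      # 10-sigma shifted profile
    out <- removeOutlierSamples(e)
    expect_equal(out$dropped, "S7")

    e2 <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
    expect_warning(res2 <- removeOutlierSamples(e2), "few samples")
    expect_equal(ncol(res2$expr), 2L)
})

test_that("soft threshold search matches closed forms and an oracle", {
    # duplicated genes: |r| = 1, connectivity = nGenes - 1 at beta = 1
    base <- rnorm(40)
    e <- rbind(g1 = base, g2 = base * 2 + 5, g3 = -base, g4 = base * 0.1)
    colnames(e) <- paste0("S", 1:40)
    a <- softAdjacency(e, 1)
    diag(a) <- 0
    expect_equal(unname(rowSums(a)), rep(3, 4), tolerance = 1e-12)

    # scale-free fit equals an independently binned computation
    set.seed(9)
    e2 <- matrix(rnorm(20 * 50), 20, 50,
                 dimnames = list(paste0("g", 1:20), paste0("S", 1:50)))
    st <- pickSoftThreshold(e2, powers = c(2, 6), nBins = 10)
    for (i in 1:2) {
        aa <- abs(cor(t(e2)))^st$powers[i]
        diag(aa) <- 0
        k <- rowSums(aa)
        br <- seq(min(k), max(k), length.out = 11L)
        bin <- cut(k, br, include.lowest = TRUE)
        dk <- tapply(k, bin, mean); pk <- tapply(k, bin, length) / 20
        ok <- !is.na(dk) & pk > 0
        fitlm <- lm(log10(pk[ok]) ~ log10(dk[ok]))
        r2 <- -sign(coef(fitlm)[2]) * summary(fitlm)$r.squared
        expect_equal(st$fitR2[i], unname(r2), tolerance = 1e-10)
    }
    expect_error(pickSoftThreshold(e2[1:2, ]), ">= 3 genes")
})

test_that("modular expression reaches a scale-free fit by power <= 20", {
    hit <- vapply(1:20, function(s) {
        cfg <- simConfig(nSamples = 100, nSnps = 50, nChrom = 1,
                         nGenes = 200,
                         modules = data.frame(size = c(30, 20, 15),
                                              rTarget = c(0.3, 0.2, 0.1)),
                         moduleNoiseSd = 0.3, seed = 800 + s)
        gt <- simulateGenotypes(cfg)
        tr <- simulateTrait(gt, cfg)
        ex <- simulateExpression(tr$truth$repeatableValue, cfg)
        g <- names(ex$truth$geneModule)[
            ex$truth$geneModule != "enzyme_panel"]
        st <- pickSoftThreshold(ex$expr[g, ], r2Target = 0.8)
        max(st$fitR2) >= 0.8
    }, logical(1))
    expect_gte(sum(hit), 16)
})

test_that("TOM matches closed forms and a triple-loop oracle", {
    # isolated pair with a_ij = 1
    a <- diag(3)
    a[1, 2] <- a[2, 1] <- 1
    tm <- tomMatrix(a)
    expect_equal(tm[1, 2], 1)
    # fully disconnected
    expect_true(all(tomMatrix(diag(4))[upper.tri(diag(4))] == 0))
    # random 12-gene adjacency vs brute force
    set.seed(3)
    r <- matrix(runif(144), 12)
    a12 <- (r + t(r)) / 2
    diag(a12) <- 1
    expect_equal(unname(tomMatrix(a12)), tomOracle(a12),
                 tolerance = 1e-12)
    expect_error(tomMatrix(matrix(runif(9), 3)), "symmetric")
})

test_that("TOM entries live in [0,1] and stay symmetric on random input", {
    for (s in 1:25) {
        set.seed(s)
        r <- matrix(runif(64), 8)
        a <- (r + t(r)) / 2
        diag(a) <- 1
        tm <- tomMatrix(a)
        expect_true(isSymmetric(tm, tol = 1e-12))
        expect_true(all(tm >= -1e-12 & tm <= 1 + 1e-12))
    }
})

test_that("planted modules are recovered with high adjusted Rand index", {
    aris <- vapply(1:20, function(s) {
        set.seed(1000 + s)
        n <- 100
        sizes <- c(20, 15, 10)
        truth <- rep(c("m1", "m2", "m3"), sizes)
        # within-module correlation 0.8, between-module 0
        e <- do.call(rbind, lapply(seq_along(sizes), function(m) {
            f <- rnorm(n)
            t(vapply(seq_len(sizes[m]), function(i)
                f + 0.5 * rnorm(n), numeric(n)))
        }))
        rownames(e) <- paste0("g", seq_len(sum(sizes)))
        colnames(e) <- paste0("S", 1:n)
        adj <- softAdjacency(e, 6)
        colors <- detectModules(tomMatrix(adj), minModuleSize = 5)
        ari(colors, truth)
    }, numeric(1))
    expect_gte(mean(aris >= 0.8), 18 / 20)
})

test_that("independent genes end up almost entirely grey", {
    greyFrac <- vapply(1:10, function(s) {
        set.seed(1100 + s)
        e <- matrix(rnorm(40 * 80), 40, 80,
                    dimnames = list(paste0("g", 1:40), paste0("S", 1:80)))
        colors <- detectModules(tomMatrix(softAdjacency(e, 6)),
                                minModuleSize = 5)
        mean(colors == "grey")
    }, numeric(1))
    expect_gte(mean(greyFrac), 0.9)
})

test_that("module sizes respect the minimum and labels rank by size", {
    set.seed(12)
    n <- 60
    f1 <- rnorm(n); f2 <- rnorm(n)
    e <- rbind(t(vapply(1:12, function(i) f1 + 0.4 * rnorm(n),
                        numeric(n))),
               t(vapply(1:6, function(i) f2 + 0.4 * rnorm(n),
                        numeric(n))),
               matrix(rnorm(8 * n), 8, n))
    rownames(e) <- paste0("g", 1:26)
    colnames(e) <- paste0("S", 1:n)
    colors <- detectModules(tomMatrix(softAdjacency(e, 6)),
                            minModuleSize = 5)
    tab <- table(colors[colors != "grey"])
    expect_true(all(tab >= 5))
    # largest module gets the first ladder color
    expect_equal(names(which.max(tab)), "turquoise")
})

test_that("module-trait statistics match analytic expectations", {
    n <- 50
    set.seed(4)
    trait <- setNames(rnorm(n), paste0("S", 1:n))
    # module constructed exactly equal to the trait
    e <- rbind(g1 = trait, g2 = trait)
    mt <- moduleTrait(c(g1 = "m", g2 = "m"), e, trait)
    expect_equal(abs(mt@stats$r), 1, tolerance = 1e-12)
    expect_lt(mt@stats$p, 1e-30)

    # p from the t transform equals the incomplete-beta evaluation
    r <- 0.85; nn <- 42
    pt_ <- gwasFunnel:::.corPvalue(r, nn)
    pbeta_ <- pbeta(1 - r^2, (nn - 2) / 2, 0.5)
    expect_equal(pt_, pbeta_, tolerance = 1e-10)
})

test_that("hub selection ranks by thresholded intramodular connectivity", {
    g <- paste0("g", 1:5)
    a <- matrix(0, 5, 5, dimnames = list(g, g))
    a[1, 2:5] <- a[2:5, 1] <- 0.9           # star around g1
    diag(a) <- 1
    hubs <- selectHubs(g, a, weightMin = 0.4, topK = 5)
    expect_equal(hubs$gene[1], "g1")
    expect_equal(nrow(hubs), 5L)            # fewer than topK: all back

    # 10-gene fixture vs brute-force weighted-degree ordering
    set.seed(21)
    g10 <- paste0("h", sprintf("%02d", 1:10))
    r <- matrix(runif(100, 0, 1), 10, dimnames = list(g10, g10))
    a10 <- (r + t(r)) / 2; diag(a10) <- 1
    hubs10 <- selectHubs(g10, a10, weightMin = 0.4, topK = 5)
    aa <- a10; diag(aa) <- 0; aa[aa <= 0.4] <- 0
    k <- rowSums(aa)
    expected <- g10[order(-k, g10)][1:5]
    expect_equal(hubs10$gene, expected)

    # nothing above the threshold
    weak <- matrix(0.1, 3, 3,
                   dimnames = list(paste0("w", 1:3), paste0("w", 1:3)))
    diag(weak) <- 1
    expect_message(h0 <- selectHubs(rownames(weak), weak, 0.4, 5),
                   "no intramodular edge")
    expect_equal(nrow(h0), 0L)
})

test_that("module detection is deterministic for identical input", {
    set.seed(30)
    e <- matrix(rnorm(30 * 40), 30, 40,
                dimnames = list(paste0("g", 1:30), paste0("S", 1:40)))
    c1 <- detectModules(tomMatrix(softAdjacency(e, 6)))
    c2 <- detectModules(tomMatrix(softAdjacency(e, 6)))
    expect_identical(c1, c2)
})
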