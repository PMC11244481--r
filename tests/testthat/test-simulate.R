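test_that("genotype generator is deterministic under a fixed seed", {
    cfg <- simConfig(nSamples = 40, nSnps = 100, nChrom = 2, seed = 5)
    g1 <- simulateGenotypes(cfg)
    g2 <- simulateGenotypes(cfg)
    expect_identical(dosage(g1), dosage(g2))
    t1 <- simulateTrait(g1, cfg)
    t2 <- simulateTrait(g2, cfg)
    expect_identical(t1$traits, t2$traits)
})

test_that("independent SNPs show only sampling-level pairwise r2", {
    cfg <- simConfig(nSamples = 200, nSnps = 120, nChrom = 2,
                     ldRho = 0, nSubpops = 1, fst = 0, seed = 3)
    gt <- simulateGenotypes(cfg)
    r <- cor(t(dosage(gt)))
    r2 <- r[upper.tri(r)]^2
    # E[r^2] under independence is ~ 1/(n-1)
    expect_lt(abs(mean(r2) - 1 / (200 - 1)), 2e-3)
})

test_that("strong within-block copula correlation yields high adjacent r2", {
    vals <- vapply(1:20, function(s) {
        cfg <- simConfig(nSamples = 150, nSnps = 20, nChrom = 1,
                         ldBlockSize = 10, ldRho = 0.99, nSubpops = 1,
                         fst = 0, seed = s)
        d <- dosage(simulateGenotypes(cfg))
        mean(vapply(1:9, function(j) cor(d[j, ], d[j + 1, ])^2,
                    numeric(1)))
    }, numeric(1))
    expect_gt(mean(vals), 0.8)
})

test_that("trait generator honours degenerate and planted configurations", {
    # zero effects + zero noise: every replicate equals mu
    cfg0 <- simConfig(nSamples = 20, nSnps = 50, nChrom = 1,
                      traitCV = 0, seed = 2)
    gt0 <- simulateGenotypes(cfg0)
    tr0 <- simulateTrait(gt0, cfg0)
    expect_true(all(tr0$traits$content == cfg0$traitMean))

    # implied heritability > 1 errors
    cfgH <- simConfig(nSamples = 30, nSnps = 50, nChrom = 1,
                      traitCV = 0.01,
                      qtns = data.frame(snp = 10, beta = 5, dom = 0),
                      seed = 2)
    gtH <- simulateGenotypes(cfgH)
    expect_error(simulateTrait(gtH, cfgH), "heritability")

    # negative overdominance pushes the het group below both homozygotes
    cfgD <- simConfig(nSamples = 400, nSnps = 50, nChrom = 1,
                      traitCV = 0.3,
                      qtns = data.frame(snp = 25, beta = 0.05,
                                        dom = -0.4),
                      seed = 9)
    gtD <- simulateGenotypes(cfgD)
    trD <- simulateTrait(gtD, cfgD)
    x <- dosage(gtD)[25, ]
    gv <- trD$truth$geneticValue
    m <- tapply(gv, x, mean)
    expect_lt(m["1"], min(m["0"], m["2"]))
})

test_that("planted per-QTN PVE is realized within tolerance", {
    pves <- vapply(1:20, function(s) {
        cfg <- simConfig(nSamples = 344, nSnps = 200, nChrom = 2,
                         qtns = data.frame(snp = 50, pve = 0.25, dom = 0),
                         seed = s)
        gt <- simulateGenotypes(cfg)
        tr <- simulateTrait(gt, cfg)
        x <- dosage(gt)[50, ]
        p <- mean(x) / 2
        beta <- tr$truth$qtns$beta[1]
        2 * p * (1 - p) * beta^2 / var(tr$traits$content)
    }, numeric(1))
    expect_lt(abs(mean(pves) - 0.25), 0.07)
})

test_that("planted module factors track the trait at the target r", {
    rs <- vapply(1:20, function(s) {
        cfg <- simConfig(nSamples = 344, nSnps = 100, nChrom = 2,
                         nGenes = 60,
                         modules = data.frame(size = 10, rTarget = 0.85),
                         moduleNoiseSd = 0.5, seed = s)
        gt <- simulateGenotypes(cfg)
        tr <- simulateTrait(gt, cfg)
        ex <- simulateExpression(tr$truth$repeatableValue, cfg)
        g <- names(ex$truth$geneModule)[ex$truth$geneModule == "module1"]
        mt <- moduleTrait(setNames(rep("m", length(g)), g),
                          ex$expr[g, ], tr$truth$repeatableValue)
        abs(mt@stats$r)
    }, numeric(1))
    expect_true(all(rs > 0.75 & rs < 0.95))
})

test_that("null module-trait correlations stay at calibration level", {
    # with rTarget = 0 the eigengene-trait |r| should only rarely beat
    # the two-sided p = 0.05 critical value
    hits <- vapply(1:50, function(s) {
        cfg <- simConfig(nSamples = 100, nSnps = 50, nChrom = 1,
                         nGenes = 30,
                         modules = data.frame(size = 10, rTarget = 0),
                         seed = s)
        gt <- simulateGenotypes(cfg)
        tr <- simulateTrait(gt, cfg)
        ex <- simulateExpression(tr$truth$repeatableValue, cfg)
        g <- names(ex$truth$geneModule)[ex$truth$geneModule == "module1"]
        mt <- moduleTrait(setNames(rep("m", length(g)), g),
                          ex$expr[g, ], tr$truth$repeatableValue)
        mt@stats$p < 0.05
    }, logical(1))
    expect_lte(mean(hits), 0.20)
})

test_that("zero-inflated fixture genes are exactly the filter's prey", {
    cfg <- simConfig(nSamples = 50, nSnps = 50, nChrom = 1, nGenes = 40,
                     modules = NULL, zeroGeneFraction = 0.25, seed = 4)
    gt <- simulateGenotypes(cfg)
    tr <- suppressWarnings(simulateTrait(gt, cfg))  # tiny panel: QTN may be monomorphic
    ex <- simulateExpression(tr$truth$repeatableValue, cfg)
    zg <- ex$truth$zeroGenes
    expect_true(length(zg) > 0)
    kept <- filterExpression(ex$expr, 0.70)
    expect_false(any(zg %in% rownames(kept)))
})

test_that("simulated gene models carry analytically known ORFs", {
    cfg <- simConfig(nSamples = 10, nSnps = 60, nChrom = 2, nGenes = 6,
                     modules = NULL, seed = 8)
    gt <- simulateGenotypes(cfg)
    gm <- simulateGeneModels(gt, cfg, nCodons = 100L)
    s <- as.character(gm$mrna[[1]])
    o <- gm$orf[1, ]
    expect_equal(substr(s, o$start, o$start + 2), "ATG")
    expect_equal(substr(s, o$end - 2, o$end), "TAA")
    found <- findOrf(s, minLen = 150L)
    expect_equal(found$start, o$start)
    expect_equal(found$end, o$end)

    # third-position degenerate change inside the ORF is synonymous
    codon1 <- substr(s, o$start + 3, o$start + 5)   # first sense codon
    pos3 <- o$start + 5
    ref <- substr(s, pos3, pos3)
    deg <- c(A = "G", G = "A", C = "T", T = "C")[ref]
    cls <- classifyMutation(s, o, pos3, ref, unname(deg))
    # third-position transitions are synonymous unless the codon is
    # ATG/TGG-like; the simulated sense codons make most degenerate
    expect_true(cls$inOrf)
    expect_true(cls$class %in% c("synonymous", "non-synonymous"))

    # a 1-bp insertion inside the ORF is a frameshift
    ins <- classifyMutation(s, o, o$start + 9, substr(s, o$start + 9,
                                                      o$start + 9),
                            paste0(substr(s, o$start + 9, o$start + 9),
                                   "A"))
    expect_equal(ins$class, "frameshift")

    # upstream of the ORF start is outside
    up <- classifyMutation(s, o, o$start - 10,
                           substr(s, o$start - 10, o$start - 10), "A")
    expect_equal(up$class, "outside-ORF")
})

test_that("dataset writer emits files the package's own readers accept", {
    cfg <- simConfig(nSamples = 25, nSnps = 60, nChrom = 2, nGenes = 12,
                     modules = data.frame(size = 5, rTarget = 0.6),
                     keyEnzymePanelSize = 3, seed = 21)
    dir <- withr::local_tempdir()
    # tiny panel: a default QTN may come up monomorphic, which the
    # generator reports and neutralizes
    ds <- suppressWarnings(simulateDataset(cfg, dir))
    gt <- readVCF(ds$paths$vcf)
    expect_identical(dosage(gt), dosage(ds$genotypes))
    ex <- readExpression(ds$paths$expression)
    expect_equal(dim(ex), dim(ds$expr))
    expect_equal(unname(ex), unname(ds$expr), tolerance = 1e-12)
    tr <- readTraitTable(ds$paths$traits)
    expect_equal(nrow(tr), nrow(ds$traits))
    gr <- readGFFGenes(ds$paths$gff3)
    expect_equal(length(gr), 12L)
    fa <- readFastaSeqs(ds$paths$fasta)
    expect_equal(sort(names(fa)), sort(names(gr)))
    truth <- jsonlite::read_json(ds$paths$truth)
    expect_true(all(c("qtns", "geneModule", "enzymeIds") %in%
                    names(truth)))
})
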