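#' Configuration for the synthetic core-collection generator
#'
#' Builds a validated configuration for simulating a genotype panel with
#' LD blocks and mild population structure, a replicated quantitative
#' trait driven by planted QTNs, an expression matrix with planted
#' trait-correlated co-expression modules plus a key-enzyme gene panel,
#' and gene models with known ORFs.  Defaults emulate the structure of a
#' ginseng core collection: 344 samples, a genome-wide SNP panel
#' (down-scaled to 4,000 markers over 24 chromosomes), a root
#' ginsenoside content trait with mean 0.632 mg/g and coefficient of
#' variation 55.77%, three replicate measurements per sample, and a
#' 15-transcript key-enzyme panel co-regulated with the trait.
#'
#' @param nSamples Number of samples (cultivars).
#' @param nSnps Total number of SNPs.
#' @param nChrom Number of chromosomes the SNPs are spread over.
#' @param ldBlockSize SNPs per LD block.
#' @param ldRho Latent (Gaussian-copula) correlation within an LD block,
#'   in [0, 1).
#' @param nSubpops Number of subpopulations.
#' @param fst Balding-Nichols-type divergence of subpopulation allele
#'   frequencies (0 = no structure).
#' @param qtns \code{data.frame} of planted QTNs with columns \code{snp}
#'   (SNP index), \code{pve} (target fraction of phenotypic variance) or
#'   \code{beta} (additive effect, trait units per alt allele), and
#'   \code{dom} (dominance deviation of the heterozygote).  \code{NULL}
#'   plants two additive QTNs (PVE 0.20 and 0.15) mid-chromosome on
#'   chromosomes 3 and 17.
#' @param nGenes Number of annotated/expressed genes (the key-enzyme
#'   panel is appended on top of these).
#' @param modules \code{data.frame} of planted co-expression modules
#'   with columns \code{size} and \code{rTarget} (latent factor vs trait
#'   correlation).  Default: sizes 20/15/10 at r 0.85/0.60/-0.50.
#' @param keyEnzymePanelSize Number of key-enzyme transcripts, driven by
#'   the strongest planted module's factor.
#' @param moduleNoiseSd Gene-specific latent noise SD inside planted
#'   modules and the enzyme panel; 0.25 gives within-module
#'   correlations around 0.94, tight enough that hub edges survive the
#'   conventional adjacency cutoff at the selected soft power.
#' @param replicateCount Trait replicates per sample.
#' @param traitMean,traitCV Trait mean (mg/g) and coefficient of
#'   variation of single measurements.
#' @param repVarShare,sampleVarShare Fractions of the non-genetic trait
#'   variance assigned to the common replicate effect and the sample
#'   effect (the remainder is residual).
#' @param zeroGeneFraction Fraction of background genes given
#'   zero-inflated expression (80% zeros), exercising the zero filter.
#' @param snpSpacing Base pairs between adjacent SNPs.
#' @param seed Integer seed; every generator call derives its stream
#'   from it (base R Mersenne-Twister).
#' @return A list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nSamples = 344L, nSnps = 4000L, nChrom = 24L,
                      ldBlockSize = 20L, ldRho = 0.7, nSubpops = 2L,
                      fst = 0.05, qtns = NULL, nGenes = 2400L,
                      modules = data.frame(size = c(10L, 26L, 15L),
                                           rTarget = c(0.85, 0.6, -0.5)),
                      keyEnzymePanelSize = 15L, moduleNoiseSd = 0.25,
                      replicateCount = 3L,
                      traitMean = 0.632, traitCV = 0.5577,
                      repVarShare = 0.1, sampleVarShare = 0.45,
                      zeroGeneFraction = 0.2, snpSpacing = 25000L,
                      seed = 1L) {
    stopifnot(nSamples >= 1, nSnps >= 1, nChrom >= 1, ldBlockSize >= 1,
              nGenes >= 1, keyEnzymePanelSize >= 0, replicateCount >= 1,
              traitMean > 0, traitCV >= 0, snpSpacing >= 1,
              ldRho >= 0, ldRho < 1, fst >= 0, fst < 1, nSubpops >= 1,
              repVarShare >= 0, sampleVarShare >= 0,
              repVarShare + sampleVarShare <= 1)
    if (!is.null(modules)) {
        stopifnot(all(c("size", "rTarget") %in% names(modules)))
        if (any(abs(modules$rTarget) >= 1))
            stop("|rTarget| must be < 1")
        if (sum(modules$size) > nGenes)
            stop("module sizes exceed nGenes")
    }
    snpsPerChrom <- ceiling(nSnps / nChrom)
    if (is.null(qtns)) {
        mid <- function(chr) (min(chr, nChrom) - 1L) * snpsPerChrom +
            max(1L, snpsPerChrom %/% 2L)
        qtns <- data.frame(snp = c(mid(3L), mid(17L)),
                           pve = c(0.20, 0.15), dom = c(0, 0))
        qtns <- qtns[qtns$snp <= nSnps, , drop = FALSE]
    }
    stopifnot("snp" %in% names(qtns),
              all(qtns$snp >= 1 & qtns$snp <= nSnps))
    structure(list(nSamples = as.integer(nSamples),
                   nSnps = as.integer(nSnps), nChrom = as.integer(nChrom),
                   ldBlockSize = as.integer(ldBlockSize), ldRho = ldRho,
                   nSubpops = as.integer(nSubpops), fst = fst,
                   qtns = qtns, nGenes = as.integer(nGenes),
                   modules = modules,
                   keyEnzymePanelSize = as.integer(keyEnzymePanelSize),
                   moduleNoiseSd = moduleNoiseSd,
                   replicateCount = as.integer(replicateCount),
                   traitMean = traitMean, traitCV = traitCV,
                   repVarShare = repVarShare,
                   sampleVarShare = sampleVarShare,
                   zeroGeneFraction = zeroGeneFraction,
                   snpSpacing = as.integer(snpSpacing),
                   seed = as.integer(seed)),
              class = "SimConfig")
}

## Seed-stream discipline: each generator stage seeds base R's
## Mersenne-Twister at config$seed + a fixed per-stage offset so stages
## are individually reproducible and mutually independent.
.seedOffset <- c(genotypes = 0L, trait = 1L, expression = 2L, genes = 3L)

## deterministic SNP coordinates implied by a config (no RNG)
.snpCoords <- function(config, idx = seq_len(config$nSnps)) {
    spc <- ceiling(config$nSnps / config$nChrom)
    data.frame(snp = sprintf("snp%06d", idx),
               chrom = paste0("chr", (idx - 1L) %/% spc + 1L),
               pos = (((idx - 1L) %% spc) + 1L) * config$snpSpacing,
               stringsAsFactors = FALSE)
}

## deterministic gene tiling implied by a config (no RNG); genes are
## laid out uniformly so QTN flanking windows contain a predictable
## set.  Gene extents are scaled with the marker spacing (2 x spacing)
## so each gene carries a realistic number of variants despite the
## thinned desk-scale panel.
.tileGenes <- function(config) {
    spc <- ceiling(config$nSnps / config$nChrom)
    extent <- (spc + 1L) * config$snpSpacing
    perChrom <- ceiling(config$nGenes / config$nChrom)
    geneLen <- 2L * config$snpSpacing
    spacing <- max(geneLen + 1000L, extent %/% perChrom)
    i <- seq_len(config$nGenes)
    chromIdx <- (i - 1L) %/% perChrom + 1L
    j <- (i - 1L) %% perChrom + 1L
    st <- (j - 1L) * spacing + 1L
    data.frame(gene = sprintf("gene%04d", i),
               chrom = paste0("chr", chromIdx),
               start = st, end = st + geneLen - 1L, strand = "+",
               stringsAsFactors = FALSE)
}

#' Simulate a genotype panel with LD blocks and population structure
#'
#' Dosages are Hardy-Weinberg draws through a Gaussian copula: per
#' sample and gamete, a latent standard normal with exchangeable
#' correlation \code{ldRho} within each LD block is thresholded at the
#' allele-frequency quantile, and the two gamete indicators are summed.
#' Ancestral minor-allele frequencies are uniform(0.05, 0.5);
#' subpopulation frequencies come from the Balding-Nichols Beta model
#' with divergence \code{fst}.
#'
#' @param config A \code{\link{simConfig}} object.
#' @return A \linkS4class{GenotypeData} object; sample ids \code{S001}
#'   ..., SNP ids \code{snp000001} ...  Column data records the
#'   subpopulation of each sample.
#' @export
simulateGenotypes <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + .seedOffset[["genotypes"]])
    n <- config$nSamples
    m <- config$nSnps
    spc <- ceiling(m / config$nChrom)
    chrom <- paste0("chr", rep(seq_len(config$nChrom), each = spc))[seq_len(m)]
    within <- (seq_len(m) - 1L) %% spc
    pos <- (within + 1L) * config$snpSpacing
    ## ancestral frequency is shared within an LD block (as for SNPs on
    ## one haplotype background); blocks draw uniform(0.05, 0.5)
    blk0 <- paste(chrom, (seq_len(m) - 1L) %/% config$ldBlockSize)
    ublk <- unique(blk0)
    pBlk <- runif(length(ublk), 0.05, 0.5)
    p0 <- pBlk[match(blk0, ublk)]
    subpop <- rep_len(seq_len(config$nSubpops), n)
    ## Balding-Nichols subpopulation frequencies
    pk <- matrix(p0, nrow = config$nSubpops, ncol = m, byrow = TRUE)
    if (config$fst > 0 && config$nSubpops > 1L) {
        a <- p0 * (1 - config$fst) / config$fst
        b <- (1 - p0) * (1 - config$fst) / config$fst
        for (k in seq_len(config$nSubpops))
            pk[k, ] <- rbeta(m, a, b)
        pk <- pmin(pmax(pk, 0.01), 0.99)
    }
    rho <- config$ldRho
    block <- (seq_len(m) - 1L) %/% config$ldBlockSize  # blocks within chrom
    block <- paste(chrom, block)
    d <- matrix(0L, n, m)
    for (g in 1:2) {   # two gametes
        z <- matrix(rnorm(n * m), n, m)
        if (rho > 0) {
            for (b in unique(block)) {
                idx <- which(block == b)
                shared <- rnorm(n)
                z[, idx] <- sqrt(rho) * shared +
                    sqrt(1 - rho) * z[, idx, drop = FALSE]
            }
        }
        thr <- qnorm(t(pk)[, subpop, drop = FALSE])  # m x n
        d <- d + (z < t(thr))
    }
    storage.mode(d) <- "integer"
    rownames(d) <- sprintf("S%03d", seq_len(n))
    dm <- t(d)
    rownames(dm) <- sprintf("snp%06d", seq_len(m))
    colnames(dm) <- sprintf("S%03d", seq_len(n))
    ref <- rep(c("A", "C", "G", "T"), length.out = m)
    alt <- rep(c("G", "T", "A", "C"), length.out = m)
    gt <- GenotypeData(dm, chrom = chrom, pos = pos, ref = ref, alt = alt)
    SummarizedExperiment::colData(gt)$subpop <- subpop
    gt
}

#' Simulate a replicated trait from planted QTNs
#'
#' Per-sample genetic value \eqn{g_i = \sum_k \beta_k x_{ik} + d_k
#' 1[x_{ik}=1]}; measurements are \eqn{y_{ir} = \mu + g_i + u_i + r_r +
#' e_{ir}} with Gaussian sample effect, common replicate effect and
#' residual, clipped at 0 mg/g.  When a QTN specifies \code{pve} rather
#' than \code{beta}, \eqn{\beta = \sqrt{PVE \cdot Var(y) / 2\hat p(1-\hat
#' p)}} using the realized allele frequency and the target phenotypic
#' variance \eqn{(CV \cdot \mu)^2}.
#'
#' @param genotypes A \linkS4class{GenotypeData} from
#'   \code{\link{simulateGenotypes}}.
#' @param config The same \code{\link{simConfig}}.
#' @return List with \code{traits} (data.frame \code{sample},
#'   \code{rep}, \code{content}) and \code{truth} (planted QTN table
#'   with realized \code{beta} and MAF, variance components, per-sample
#'   genetic and repeatable values).
#' @export
simulateTrait <- function(genotypes, config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + .seedOffset[["trait"]])
    d <- dosage(genotypes)
    n <- ncol(d)
    mu <- config$traitMean
    varY <- (config$traitCV * mu)^2
    q <- config$qtns
    q$beta <- if ("beta" %in% names(q)) q$beta else NA_real_
    if (is.null(q$dom)) q$dom <- 0
    q$maf <- NA_real_
    for (k in seq_len(nrow(q))) {
        x <- d[q$snp[k], ]
        ph <- mean(x) / 2
        q$maf[k] <- min(ph, 1 - ph)
        if (is.na(q$beta[k])) {
            if (!"pve" %in% names(q) || is.na(q$pve[k]))
                stop("QTN needs either beta or pve")
            if (ph <= 0 || ph >= 1) {
                warning("planted QTN ", q$snp[k],
                        " is monomorphic in this draw; effect set to 0")
                q$beta[k] <- 0
            } else {
                q$beta[k] <- sqrt(q$pve[k] * varY / (2 * ph * (1 - ph)))
            }
        }
    }
    g <- rep(0, n)
    for (k in seq_len(nrow(q))) {
        x <- d[q$snp[k], ]
        g <- g + q$beta[k] * x + q$dom[k] * (x == 1)
    }
    varG <- var(g) * (n - 1) / n
    if (varG > varY)
        stop("planted genetic variance exceeds the target phenotypic ",
             "variance (implied heritability > 1)")
    rem <- varY - varG
    s2u <- config$sampleVarShare / (config$sampleVarShare +
        config$repVarShare + (1 - config$sampleVarShare -
        config$repVarShare)) * rem
    s2r <- config$repVarShare * rem
    s2e <- rem - s2u - s2r
    u <- rnorm(n, 0, sqrt(s2u))
    rEff <- rnorm(config$replicateCount, 0, sqrt(s2r))
    ids <- colnames(d)
    recs <- expand.grid(sample = ids, rep = seq_len(config$replicateCount),
                        stringsAsFactors = FALSE)
    e <- rnorm(nrow(recs), 0, sqrt(s2e))
    yval <- mu + g[match(recs$sample, ids)] + u[match(recs$sample, ids)] +
        rEff[recs$rep] + e
    recs$content <- pmax(yval, 0)
    q$id <- rownames(d)[q$snp]
    truth <- list(qtns = q,
                  varcomp = c(sample = s2u, rep = s2r, residual = s2e,
                              genetic = varG),
                  geneticValue = setNames(g, ids),
                  repeatableValue = setNames(mu + g + u, ids))
    list(traits = recs, truth = truth)
}

#' Simulate an expression matrix with planted trait-correlated modules
#'
#' Each planted module is driven by a latent factor \eqn{f_m = r\,
#' \tilde t + \sqrt{1-r^2}\, \epsilon} where \eqn{\tilde t} is the
#' standardized repeatable trait value; member genes are \eqn{f_m}
#' plus gene noise (within-module latent correlation about 0.8), mapped
#' to non-negative expression through an exponential link.  Background
#' genes are independent noise; a configurable fraction of them is
#' zero-inflated (80% zeros).  Key-enzyme panel transcripts (ids
#' \code{KE01}...) are extra rows driven by the strongest module's
#' factor.
#'
#' @param trait Named per-sample trait values the modules should track
#'   (typically \code{truth$repeatableValue} from
#'   \code{\link{simulateTrait}}).
#' @param config The \code{\link{simConfig}}.
#' @return List with \code{expr} (matrix, genes+panel x samples) and
#'   \code{truth} (gene -> module map, module factor-trait target r,
#'   enzyme panel ids).
#' @export
simulateExpression <- function(trait, config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + .seedOffset[["expression"]])
    n <- length(trait)
    tt <- as.numeric(scale(trait))
    mods <- config$modules
    nG <- config$nGenes
    geneIds <- sprintf("gene%04d", seq_len(nG))
    assign <- setNames(rep("background", nG), geneIds)
    lat <- matrix(rnorm(nG * n), nG, n)       # gene-specific noise
    X <- lat
    factors <- list()
    ## module genes are seeded inside the planted QTN flanking windows
    ## (module m <- window of QTN m) so the association funnel and the
    ## co-expression funnel converge on the same genes by construction;
    ## leftover membership is filled from the remaining gene pool.
    tiles <- .tileGenes(config)
    qc <- .snpCoords(config, config$qtns$snp)
    free <- rep(TRUE, nG)
    if (!is.null(mods) && nrow(mods)) {
        for (m in seq_len(nrow(mods))) {
            r <- mods$rTarget[m]
            f <- r * tt + sqrt(1 - r^2) * rnorm(n)
            factors[[m]] <- f
            idx <- integer(0)
            if (m <= nrow(qc)) {
                inWin <- which(tiles$chrom == qc$chrom[m] &
                               tiles$end >= qc$pos[m] - 500000L &
                               tiles$start <= qc$pos[m] + 500000L & free)
                idx <- head(inWin, mods$size[m])
            }
            need <- mods$size[m] - length(idx)
            if (need > 0) {
                pool <- which(free)
                pool <- setdiff(pool, idx)
                idx <- c(idx, head(pool, need))
            }
            free[idx] <- FALSE
            X[idx, ] <- matrix(rep(f, each = length(idx)),
                               length(idx), n) +
                config$moduleNoiseSd * lat[idx, , drop = FALSE]
            assign[idx] <- paste0("module", m)
        }
    }
    ## zero-inflate part of the background to exercise the 70% filter
    bg <- which(assign == "background")
    nZero <- round(config$zeroGeneFraction * length(bg))
    zeroGenes <- if (nZero > 0) bg[seq_len(nZero)] else integer(0)
    expr <- exp(0.3 * X + 1)
    for (i in zeroGenes) {
        off <- sample.int(n, size = round(0.8 * n))
        expr[i, off] <- 0
    }
    rownames(expr) <- geneIds
    colnames(expr) <- names(trait)
    if (config$keyEnzymePanelSize > 0) {
        strongest <- if (length(factors))
            which.max(abs(mods$rTarget)) else NA_integer_
        f <- if (!is.na(strongest)) factors[[strongest]] else rnorm(n)
        ke <- matrix(rep(f, each = config$keyEnzymePanelSize),
                     config$keyEnzymePanelSize, n) +
            config$moduleNoiseSd *
                matrix(rnorm(config$keyEnzymePanelSize * n),
                         config$keyEnzymePanelSize, n)
        keExpr <- exp(0.3 * ke + 1)
        rownames(keExpr) <- sprintf("KE%02d",
                                    seq_len(config$keyEnzymePanelSize))
        colnames(keExpr) <- names(trait)
        expr <- rbind(expr, keExpr)
        assign <- c(assign, setNames(rep("enzyme_panel",
                                         config$keyEnzymePanelSize),
                                     rownames(keExpr)))
    }
    truth <- list(geneModule = assign,
                  moduleR = if (!is.null(mods))
                      setNames(mods$rTarget,
                               paste0("module", seq_len(nrow(mods))))
                  else numeric(0),
                  enzymeIds = grep("^KE", rownames(expr), value = TRUE),
                  zeroGenes = geneIds[zeroGenes])
    list(expr = expr, truth = truth)
}

#' Simulate gene models and mRNA sequences with known ORFs
#'
#' Genes are tiled uniformly along the simulated chromosomes (so QTN
#' flanking windows contain a predictable number of genes).  Every gene
#' gets an mRNA with a single known ORF: a 100-nt 5' UTR free of ATG, an
#' ATG-initiated coding region of \code{nCodons} sense codons plus a TAA
#' stop, and a 100-nt 3' UTR, so the consequence class of any planted
#' variant is analytically known.
#'
#' @param genotypes A \linkS4class{GenotypeData} (defines chromosome
#'   extents).
#' @param config The \code{\link{simConfig}}.
#' @param nCodons Number of sense codons in each ORF; \code{NULL}
#'   (default) sizes the ORF to span the gene so that in-gene variants
#'   mostly fall inside it.
#' @return List with \code{genes} (\code{GRanges}, names = gene ids),
#'   \code{mrna} (\code{DNAStringSet}) and \code{orf} (data.frame
#'   \code{gene}, \code{start}, \code{end}, 1-based inclusive within the
#'   mRNA, stop codon included).
#' @export
simulateGeneModels <- function(genotypes, config, nCodons = NULL) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + .seedOffset[["genes"]])
    tab <- .tileGenes(config)
    if (is.null(nCodons))
        nCodons <- max(50L, (tab$end[1L] - tab$start[1L] + 1L - 206L) %/% 3L)
    genes <- GenomicRanges::GRanges(tab$chrom,
                                    IRanges::IRanges(tab$start, tab$end),
                                    strand = tab$strand)
    names(genes) <- tab$gene
    ## mRNA with one known ORF per gene
    utrAlphabet <- c("C", "T", "G")          # no A -> no ATG, no TAA/TAG/TGA risk
    senseCodons <- setdiff(
        apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                          c("A", "C", "G", "T")), 1L, paste, collapse = ""),
        c("TAA", "TAG", "TGA"))
    nG <- config$nGenes
    ## per-gene assembly (index sampling + one paste) keeps memory flat
    ## even for thousands of long transcripts
    seqs <- vapply(seq_len(nG), function(i) {
        utr5 <- paste(utrAlphabet[sample.int(3L, 100L, replace = TRUE)],
                      collapse = "")
        cds <- paste(senseCodons[sample.int(length(senseCodons), nCodons,
                                            replace = TRUE)],
                     collapse = "")
        utr3 <- paste(utrAlphabet[sample.int(3L, 100L, replace = TRUE)],
                      collapse = "")
        paste0(utr5, "ATG", cds, "TAA", utr3)
    }, character(1))
    mrna <- Biostrings::DNAStringSet(seqs)
    names(mrna) <- tab$gene
    orf <- data.frame(gene = tab$gene, start = 101L,
                      end = 101L + 3L * (nCodons + 1L) + 2L)
    list(genes = genes, mrna = mrna, orf = orf)
}

#' Simulate and write a complete synthetic dataset
#'
#' Runs all four generators under one configuration and writes the
#' pipeline's input formats (VCF, GFF3, FASTA, expression TSV, trait
#' TSV) plus a JSON ground-truth ledger sufficient to score QTN
#' recovery, module recovery and consequence-class recovery without
#' re-simulation.
#'
#' @param config A \code{\link{simConfig}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (\code{genotypes},
#'   \code{traits}, \code{expr}, \code{genes}, \code{mrna}, \code{truth})
#'   and the file paths written.
#' @export
simulateDataset <- function(config, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gt <- simulateGenotypes(config)
    tr <- simulateTrait(gt, config)
    ex <- simulateExpression(tr$truth$repeatableValue, config)
    gm <- simulateGeneModels(gt, config)
    paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                  traits = file.path(dir, "traits.tsv"),
                  expression = file.path(dir, "expression.tsv"),
                  gff3 = file.path(dir, "genes.gff3"),
                  fasta = file.path(dir, "mrna.fasta"),
                  truth = file.path(dir, "truth.json"))
    writeVCF(gt, paths$vcf)
    writeFunnelTable(tr$traits, paths$traits)
    writeExpression(ex$expr, paths$expression)
    gdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(gm$genes)),
                      src = "gwasFunnel", type = "gene",
                      start = GenomicRanges::start(gm$genes),
                      end = GenomicRanges::end(gm$genes), score = ".",
                      strand = as.character(GenomicRanges::strand(gm$genes)),
                      phase = ".",
                      attr = paste0("ID=", names(gm$genes)))
    writeLines(c("##gff-version 3",
                 do.call(paste, c(gdf, sep = "\t"))), paths$gff3)
    Biostrings::writeXStringSet(gm$mrna, paths$fasta)
    truth <- list(qtns = tr$truth$qtns, varcomp = as.list(tr$truth$varcomp),
                  geneticValue = as.list(tr$truth$geneticValue),
                  repeatableValue = as.list(tr$truth$repeatableValue),
                  geneModule = as.list(ex$truth$geneModule),
                  moduleR = as.list(ex$truth$moduleR),
                  enzymeIds = ex$truth$enzymeIds,
                  orf = gm$orf, seed = config$seed)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    invisible(list(genotypes = gt, traits = tr$traits,
                   truthTrait = tr$truth, expr = ex$expr,
                   truthExpr = ex$truth, genes = gm$genes, mrna = gm$mrna,
                   orf = gm$orf, paths = paths))
}
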