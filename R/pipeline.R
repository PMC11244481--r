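#' Run the candidate-gene funnel end-to-end on synthetic data
#'
#' Executes every stage in order on one generated dataset: simulate ->
#' BLUP -> single-locus GWAS (six models) -> multi-locus GWAS -> QTN
#' intersection and gene windows (candidates I) -> weighted
#' co-expression modules and hubs (candidates II) -> per-SNP trait
#' tests with ORF consequence classes (candidates III) -> key-enzyme
#' correlation networks (confirmed / key candidates) -> genetic-effect
#' classification, writing each stage's tables plus a JSON manifest
#' (input hashes, parameters, seed, per-stage candidate counts) under
#' \code{outdir}.  Identical config and seed give byte-identical
#' outputs.
#'
#' @param config A \code{\link{simConfig}}; its \code{seed} drives all
#'   randomness.
#' @param outdir Output directory.
#' @param fwer Family-wise error rate for the Bonferroni threshold
#'   (default 0.01).
#' @param qQ,qPCA Structure covariate dimensions for the Q-style and
#'   PCA-style models.
#' @param pruneWindow,pruneStep,pruneR2 LD pruning parameters (the
#'   pruned panel is used for kinship and PCs; all SNPs are scanned).
#' @param stage1P,lodMin Multi-locus scan parameters.
#' @param mergeGap Locus merge / cross-model match distance (bp).
#' @param flank QTN window half-width (bp).
#' @param zeroFraction WGCNA zero-expression filter.
#' @param powers,r2Target Soft-threshold search grid and target fit.
#'   The pipeline grid stops at 12: on the few dozen genes of a
#'   QTN-window panel the binned scale-free fit is noisy and its argmax
#'   drifts to the top of the grid, where adjacency degenerates toward
#'   zero and no hub edge can clear the weight cutoff.  The full 1-20
#'   grid remains the \code{\link{pickSoftThreshold}} default.
#' @param weightMin,topK Hub-gene selection parameters.
#' @param alpha Per-SNP trait-test significance level.
#' @param pConfirm,pKey Network thresholds for confirmed / key
#'   candidate calling.
#' @param groupSize High/Mid/Low group size for the group-network
#'   comparison.
#' @return Invisibly, a list with every stage's in-memory results and
#'   the manifest.
#' @export
runPipeline <- function(config = simConfig(), outdir,
                        fwer = 0.01, qQ = 2L, qPCA = 3L,
                        pruneWindow = 50L, pruneStep = 50L,
                        pruneR2 = 0.2, stage1P = 0.01, lodMin = 3.0,
                        mergeGap = 20000L, flank = 500000L,
                        zeroFraction = 0.70,
                        powers = seq(1, 12, by = 0.5), r2Target = 0.85,
                        weightMin = 0.4, topK = 5L, alpha = 0.05,
                        pConfirm = 0.05, pKey = 1e-6, groupSize = 14L) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    done <- character(0)
    stage <- function(name, expr) {
        res <- tryCatch(force(expr), error = function(e)
            stop(sprintf("stage '%s' failed (completed: %s): %s", name,
                         paste(done, collapse = ", "),
                         conditionMessage(e)), call. = FALSE))
        done <<- c(done, name)
        res
    }
    sim <- stage("simulate", simulateDataset(config, file.path(outdir,
                                                               "input")))
    fit <- stage("blup", fitBlup(sim$traits))
    bl <- blup(fit)
    writeFunnelTable(data.frame(sample = names(bl), blup = bl),
                     file.path(outdir, "blup.tsv"))
    ks <- ksNormality(bl)

    gtAll <- sim$genotypes
    single <- stage("gwas-single", {
        pruned <- ldPrune(gtAll, pruneWindow, pruneStep, pruneR2)
        gtP <- gtAll[snpInfo(gtAll)$id %in% pruned, ]
        K <- computeKinship(gtP)
        pcQ <- computePCs(gtP, qQ)
        pcP <- computePCs(gtP, qPCA)
        res <- rbind(glmScan(gtAll, bl, NULL, "GLM"),
                     glmScan(gtAll, bl, pcQ, "GLM_Q"),
                     glmScan(gtAll, bl, pcP, "GLM_PCA"),
                     mlmScan(gtAll, bl, K, NULL, "MLM_K"),
                     mlmScan(gtAll, bl, K, pcQ, "MLM_QK"),
                     mlmScan(gtAll, bl, K, pcP, "MLM_PCAK"))
        list(results = res, kinship = K, pruned = pruned)
    })
    writeFunnelTable(single$results, file.path(outdir, "gwas_single.tsv"))
    writeLines(single$pruned, file.path(outdir, "pruned_snps.txt"))
    thr <- bonferroniThreshold(nrow(snpInfo(gtAll)), fwer)
    tags <- c("GLM", "GLM_Q", "GLM_PCA", "MLM_K", "MLM_QK", "MLM_PCAK")
    perModel <- lapply(setNames(tags, tags), function(tg) {
        h <- single$results[single$results$model == tg &
                            single$results$p <= thr$p, , drop = FALSE]
        mergeLoci(h, maxGap = mergeGap)
    })
    for (tg in tags)
        manhattanQQPlot(single$results[single$results$model == tg, ],
                        thr$p, file.path(outdir,
                                         paste0("manhattan_", tg, ".png")))

    multi <- stage("gwas-multi",
                   multilocusScan(gtAll, bl, single$kinship,
                                  stage1P = stage1P, lodMin = lodMin))
    writeFunnelTable(multi, file.path(outdir, "gwas_multi.tsv"))
    perModel$ML <- mergeLoci(multi, maxGap = mergeGap)

    qtns <- stage("funnel", intersectModels(
        perModel, list(single_locus = tags, multi_locus = "ML"),
        maxGap = mergeGap))
    writeFunnelTable(qtns, file.path(outdir, "qtns.tsv"))
    candI <- stage("windows",
                   genesInWindows(qtns, sim$genes, flank = flank))
    writeFunnelTable(candI, file.path(outdir, "candidates_I.tsv"))

    wg <- candII <- NULL
    if (nrow(candI) > 0L) {
        wg <- stage("wgcna", {
            e0 <- sim$expr[intersect(candI$gene, rownames(sim$expr)), ,
                           drop = FALSE]
            nBefore <- nrow(e0)
            e1 <- filterExpression(e0, zeroFraction)
            out <- removeOutlierSamples(e1)
            st <- pickSoftThreshold(out$expr, powers, r2Target)
            adj <- softAdjacency(out$expr, st$power)
            tom <- tomMatrix(adj)
            colors <- detectModules(tom)
            mt <- moduleTrait(colors, out$expr, bl, power = st$power)
            keyMod <- if (nrow(mt@stats))
                mt@stats$module[which.max(abs(mt@stats$r))] else NA
            hubs <- if (!is.na(keyMod))
                selectHubs(names(colors)[colors == keyMod], adj,
                           weightMin, topK) else NULL
            list(nBefore = nBefore, nAfter = nrow(e1),
                 dropped = out$dropped, soft = st, adjacency = adj,
                 modules = mt, keyModule = keyMod, hubs = hubs)
        })
        if (!is.null(wg$hubs) && nrow(wg$hubs)) candII <- wg$hubs$gene
        writeFunnelTable(
            data.frame(gene = names(moduleColors(wg$modules)),
                       module = unname(moduleColors(wg$modules))),
            file.path(outdir, "modules.tsv"))
        writeFunnelTable(wg$modules@stats,
                         file.path(outdir, "module_trait.tsv"))
        if (!is.null(wg$hubs))
            writeFunnelTable(wg$hubs, file.path(outdir, "hubs.tsv"))
    }

    snpStats <- candIII <- NULL
    if (!is.null(candII)) {
        snpStats <- stage("snp-effect", {
            info <- snpInfo(gtAll)
            gm <- sim$genes[candII]
            rows <- list()
            for (g in candII) {
                sel <- info$chrom ==
                    as.character(GenomicRanges::seqnames(gm[g])) &
                    info$pos >= GenomicRanges::start(gm[g]) &
                    info$pos <= GenomicRanges::end(gm[g])
                for (sid in info$id[sel]) {
                    tt <- snpTraitTest(dosage(gtAll)[sid, ], bl)
                    posMrna <- info$pos[info$id == sid] -
                        GenomicRanges::start(gm[g]) + 1L
                    seqg <- as.character(sim$mrna[[g]])
                    cls <- if (posMrna <= nchar(seqg)) {
                        orf <- list(start = sim$orf$start[sim$orf$gene == g],
                                    end = sim$orf$end[sim$orf$gene == g])
                        ref <- substr(seqg, posMrna, posMrna)
                        alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
                        classifyMutation(seqg, orf, posMrna, ref, alt,
                                         gene = g)
                    } else list(inOrf = FALSE, class = "outside-ORF")
                    rows[[length(rows) + 1L]] <- data.frame(
                        snp = sid, gene = g, p = tt$p,
                        impactRate = tt$impactRate, inOrf = cls$inOrf,
                        class = cls$class, stringsAsFactors = FALSE)
                }
            }
            if (length(rows)) do.call(rbind, rows) else NULL
        })
        if (!is.null(snpStats)) {
            writeFunnelTable(snpStats, file.path(outdir, "snp_effects.tsv"))
            sigGenes <- unique(snpStats$gene[!is.na(snpStats$p) &
                                             snpStats$p <= alpha])
            candIII <- sigGenes
        }
    }

    netRes <- effects <- NULL
    enzymes <- grep("^KE", rownames(sim$expr), value = TRUE)
    if (!is.null(candIII) && length(candIII)) {
        netRes <- stage("network", {
            nodesAll <- c(candIII, enzymes)
            roles <- setNames(c(rep("candidate", length(candIII)),
                                rep("enzyme", length(enzymes))), nodesAll)
            n1 <- buildNetwork(sim$expr, nodesAll, pConfirm, roles)
            n2 <- buildNetwork(sim$expr, nodesAll, pKey, roles)
            calls <- callCandidates(n1, n2, candIII, enzymes)
            writeNetwork(n1, file.path(outdir, "network_confirm"))
            writeNetwork(n2, file.path(outdir, "network_key"))
            list(confirm = n1, key = n2, calls = calls)
        })
        effects <- stage("effects", {
            rows <- list()
            info <- snpInfo(gtAll)
            for (g in netRes$calls$key) {
                gm <- sim$genes[g]
                sel <- info$chrom ==
                    as.character(GenomicRanges::seqnames(gm)) &
                    info$pos >= GenomicRanges::start(gm) &
                    info$pos <= GenomicRanges::end(gm)
                for (sid in info$id[sel]) {
                    x <- dosage(gtAll)[sid, ]
                    if (!all(0:2 %in% x)) next
                    ge <- classifyGeneticEffect(
                        bl[names(x)[x == 0 & !is.na(x)]],
                        bl[names(x)[x == 1 & !is.na(x)]],
                        bl[names(x)[x == 2 & !is.na(x)]],
                        alleles = unlist(info[info$id == sid,
                                              c("ref", "alt")]))
                    rows[[length(rows) + 1L]] <- data.frame(
                        snp = sid, gene = g, class = ge$class,
                        favorableAllele = ge$favorableAllele,
                        mAA = ge$means["AA"], mAG = ge$means["AG"],
                        mGG = ge$means["GG"],
                        p = ge$pHetVsFavorable,
                        stringsAsFactors = FALSE)
                }
            }
            if (length(rows)) do.call(rbind, rows) else NULL
        })
        if (!is.null(effects))
            writeFunnelTable(effects, file.path(outdir,
                                                "genetic_effects.tsv"))
    }

    grp <- NULL
    if (length(enzymes) && 3L * groupSize <= length(bl)) {
        grp <- stage("group-network", {
            keyG <- if (!is.null(netRes)) netRes$calls$key else character(0)
            g <- groupNetworkComparison(sim$expr, bl,
                                        nodeIds = c(keyG, enzymes),
                                        groupSize = groupSize)
            writeFunnelTable(g$summary,
                             file.path(outdir, "group_networks.tsv"))
            g
        })
    }

    manifest <- list(
        seed = config$seed,
        parameters = list(fwer = fwer, qQ = qQ, qPCA = qPCA,
                          pruneWindow = pruneWindow, pruneStep = pruneStep,
                          pruneR2 = pruneR2, stage1P = stage1P,
                          lodMin = lodMin, mergeGap = mergeGap,
                          flank = flank, zeroFraction = zeroFraction,
                          r2Target = r2Target, weightMin = weightMin,
                          topK = topK, alpha = alpha,
                          pConfirm = pConfirm, pKey = pKey,
                          groupSize = groupSize,
                          threshold = thr),
        inputHashes = as.list(tools::md5sum(unlist(sim$paths))),
        ksNormality = ks,
        counts = list(
            snps = nrow(snpInfo(gtAll)),
            prunedRetained = length(single$pruned),
            qtns = nrow(qtns),
            candidatesI = nrow(candI),
            wgcnaInput = if (!is.null(wg)) wg$nBefore else 0L,
            wgcnaFiltered = if (!is.null(wg)) wg$nAfter else 0L,
            candidatesII = length(candII),
            candidatesIII = length(candIII),
            confirmed = if (!is.null(netRes))
                length(netRes$calls$confirmed) else 0L,
            key = if (!is.null(netRes))
                length(netRes$calls$key) else 0L),
        stagesCompleted = done)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(sim = sim, blup = fit, single = single$results,
                   kinship = single$kinship, threshold = thr,
                   multi = multi, perModelLoci = perModel, qtns = qtns,
                   candidatesI = candI, wgcna = wg, candidatesII = candII,
                   snpStats = snpStats, candidatesIII = candIII,
                   network = netRes, effects = effects, groups = grp,
                   manifest = manifest))
}
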