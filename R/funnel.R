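#' Intersect significant loci across association models into QTNs
#'
#' A locus is promoted to a quantitative trait nucleotide (QTN) when a
#' locus within the merge distance exists in \emph{every} model of at
#' least one required model set (e.g. all six single-locus models, or
#' all multi-locus models).  Qualifying loci from all models are pooled
#' and deduplicated by the same \eqn{\le} \code{maxGap} single-linkage
#' chaining as \code{\link{mergeLoci}}, so cross-model matching and
#' locus merging share one distance semantics.
#'
#' @param perModelLoci Named list of locus tables (columns \code{chrom},
#'   \code{pos}, optionally \code{snp} and a score), keyed by model tag.
#' @param requiredSets List of character vectors of model tags; each
#'   vector is one "all models must agree" set.  Tags absent from
#'   \code{perModelLoci} raise an error.
#' @param maxGap Cross-model matching / merging distance in bp.
#' @return \code{data.frame}: \code{chrom}, \code{pos}, \code{snp},
#'   \code{members}, \code{n}, \code{best}, \code{supportedBy}
#'   (semicolon-joined names of the satisfied sets).  Zero rows if no
#'   locus is supported.
#' @export
intersectModels <- function(perModelLoci, requiredSets,
                            maxGap = 20000L) {
    tags <- unique(unlist(requiredSets))
    unknown <- setdiff(tags, names(perModelLoci))
    if (length(unknown))
        stop("unknown model tag(s): ", paste(unknown, collapse = ", "))
    if (is.null(names(requiredSets)))
        names(requiredSets) <- paste0("set", seq_along(requiredSets))
    matched <- function(locus, tab) {
        any(tab$chrom == locus$chrom & abs(tab$pos - locus$pos) <= maxGap)
    }
    pooled <- list()
    for (sn in names(requiredSets)) {
        set <- requiredSets[[sn]]
        cand <- do.call(rbind, lapply(set, function(tg) {
            tb <- perModelLoci[[tg]]
            if (is.null(tb) || nrow(tb) == 0L) return(NULL)
            tb[, intersect(c("chrom", "pos", "snp", "lod", "p", "best"),
                           names(tb)), drop = FALSE]
        }))
        if (is.null(cand) || nrow(cand) == 0L) next
        ok <- vapply(seq_len(nrow(cand)), function(i) {
            all(vapply(set, function(tg) {
                tb <- perModelLoci[[tg]]
                !is.null(tb) && nrow(tb) > 0L && matched(cand[i, ], tb)
            }, logical(1)))
        }, logical(1))
        if (any(ok)) {
            q <- cand[ok, , drop = FALSE]
            q$supportedBy <- sn
            pooled[[sn]] <- q
        }
    }
    if (length(pooled) == 0L)
        return(data.frame(chrom = character(0), pos = integer(0),
                          snp = character(0), members = character(0),
                          n = integer(0), best = numeric(0),
                          supportedBy = character(0),
                          stringsAsFactors = FALSE))
    allq <- do.call(rbind, pooled)
    merged <- mergeLoci(allq, maxGap = maxGap)
    merged$supportedBy <- vapply(seq_len(nrow(merged)), function(i) {
        mem <- strsplit(merged$members[i], ",", fixed = TRUE)[[1L]]
        paste(sort(unique(allq$supportedBy[allq$snp %in% mem])),
              collapse = ";")
    }, character(1))
    rownames(merged) <- NULL
    merged
}

#' Extract genes inside QTN flanking windows
#'
#' A gene qualifies when its [start, end] interval overlaps
#' [pos - flank, pos + flank] on the QTN's chromosome (overlap, not
#' containment; boundaries inclusive).  The union over all QTNs is
#' returned, deduplicated, with provenance recording which QTN(s)
#' pulled each gene in.
#'
#' @param qtns \code{data.frame} with \code{chrom}, \code{pos} and
#'   (optionally) \code{snp}.
#' @param geneModels \code{GRanges} of gene models, names = gene ids.
#' @param flank Window half-width in bp (default 500 kb).
#' @return \code{data.frame}: \code{gene}, \code{chrom}, \code{start},
#'   \code{end}, \code{qtn} (comma-separated provenance).
#' @export
genesInWindows <- function(qtns, geneModels, flank = 500000L) {
    if (nrow(qtns) == 0L)
        return(data.frame(gene = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          qtn = character(0), stringsAsFactors = FALSE))
    if (!"snp" %in% names(qtns))
        qtns$snp <- paste0(qtns$chrom, "_", qtns$pos)
    annChrom <- unique(as.character(GenomicRanges::seqnames(geneModels)))
    absent <- !(qtns$chrom %in% annChrom)
    if (any(absent)) {
        warning("QTN chromosome(s) absent from annotation, skipped: ",
                paste(unique(qtns$chrom[absent]), collapse = ", "))
        qtns <- qtns[!absent, , drop = FALSE]
        if (nrow(qtns) == 0L)
            return(data.frame(gene = character(0), chrom = character(0),
                              start = integer(0), end = integer(0),
                              qtn = character(0),
                              stringsAsFactors = FALSE))
    }
    win <- GenomicRanges::GRanges(
        qtns$chrom,
        IRanges::IRanges(start = pmax(1L, qtns$pos - flank),
                         end = qtns$pos + flank))
    ov <- GenomicRanges::findOverlaps(geneModels, win,
                                      ignore.strand = TRUE)
    if (length(ov) == 0L)
        return(data.frame(gene = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          qtn = character(0), stringsAsFactors = FALSE))
    gid <- names(geneModels)[S4Vectors::queryHits(ov)]
    qid <- qtns$snp[S4Vectors::subjectHits(ov)]
    prov <- tapply(qid, gid, function(x)
        paste(sort(unique(x)), collapse = ","))
    ug <- sort(unique(gid))
    gm <- geneModels[ug]
    data.frame(gene = ug,
               chrom = as.character(GenomicRanges::seqnames(gm)),
               start = GenomicRanges::start(gm),
               end = GenomicRanges::end(gm),
               qtn = as.character(prov[ug]),
               stringsAsFactors = FALSE, row.names = NULL)
}
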