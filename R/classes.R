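#' GenotypeData: biallelic SNP dosages with genomic coordinates
#'
#' An S4 container for a panel of biallelic SNPs typed on a sample
#' collection.  It extends \code{RangedSummarizedExperiment}: the single
#' assay \code{"dosage"} holds alt-allele counts in \{0, 1, 2, NA\}
#' (SNPs in rows, samples in columns) and the \code{rowRanges} carry the
#' 1-based positions plus \code{ref}/\code{alt} alleles in the metadata
#' columns.
#'
#' Invariants enforced by the validity method: every non-missing call is
#' 0, 1 or 2; every SNP has single-base (or, for InDels kept for
#' consequence annotation, single-allele) \code{ref} and \code{alt}
#' strings with no comma (biallelic); positions are strictly increasing
#' within each chromosome.
#'
#' @slot assays,rowRanges,colData inherited from
#'   \code{RangedSummarizedExperiment}.
#' @seealso \code{\link{GenotypeData}} (constructor), \code{\link{readVCF}},
#'   \code{\link{simulateGenotypes}}
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @exportClass GenotypeData
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        return("assay 'dosage' is required")
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- !is.na(d) & !(d %in% c(0L, 1L, 2L))
    if (any(bad))
        return("dosage calls must be 0, 1, 2 or NA")
    rr <- SummarizedExperiment::rowRanges(object)
    mc <- S4Vectors::mcols(rr)
    if (!all(c("ref", "alt") %in% colnames(mc)))
        return("rowRanges must carry 'ref' and 'alt' metadata columns")
    if (any(grepl(",", mc$alt, fixed = TRUE)))
        return("multiallelic records are not allowed")
    pos <- GenomicRanges::start(rr)
    chr <- as.character(GenomicRanges::seqnames(rr))
    for (cc in unique(chr)) {
        p <- pos[chr == cc]
        if (length(p) > 1L && any(diff(p) <= 0))
            return(sprintf("positions not strictly increasing on %s", cc))
    }
    TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage Integer matrix of alt-allele counts, SNPs in rows
#'   (rownames = SNP ids), samples in columns (colnames = sample ids);
#'   missing calls as \code{NA}.
#' @param chrom Character vector of chromosome names, one per SNP.
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Character vectors of reference / alternate alleles.
#' @return A \linkS4class{GenotypeData} object.
#' @examples
#' gt <- GenotypeData(matrix(c(0L, 1L, 2L, 0L), 2, 2,
#'                           dimnames = list(c("s1", "s2"), c("A", "B"))),
#'                    chrom = c("chr1", "chr1"), pos = c(100L, 200L),
#'                    ref = c("A", "C"), alt = c("G", "T"))
#' dosage(gt)
#' @export
GenotypeData <- function(dosage, chrom, pos, ref, alt) {
    stopifnot(is.matrix(dosage), length(chrom) == nrow(dosage),
              length(pos) == nrow(dosage), length(ref) == nrow(dosage),
              length(alt) == nrow(dosage))
    storage.mode(dosage) <- "integer"
    if (is.null(rownames(dosage)))
        rownames(dosage) <- paste0("snp", seq_len(nrow(dosage)))
    if (is.null(colnames(dosage)))
        colnames(dosage) <- paste0("S", seq_len(ncol(dosage)))
    rr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = as.integer(pos),
                                  width = nchar(ref)),
        ref = as.character(ref), alt = as.character(alt))
    names(rr) <- rownames(dosage)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage), rowRanges = rr)
    methods::new("GenotypeData", se)
}

#' @rdname dosage
#' @export
setMethod("dosage", "GenotypeData", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' @rdname snpInfo
#' @export
setMethod("snpInfo", "GenotypeData", function(x) {
    rr <- SummarizedExperiment::rowRanges(x)
    data.frame(id = names(rr),
               chrom = as.character(GenomicRanges::seqnames(rr)),
               pos = GenomicRanges::start(rr),
               ref = S4Vectors::mcols(rr)$ref,
               alt = S4Vectors::mcols(rr)$alt,
               row.names = NULL, stringsAsFactors = FALSE)
})

setMethod("show", "GenotypeData", function(object) {
    cat(sprintf("GenotypeData: %d SNPs x %d samples (%d chromosomes)\n",
                nrow(object), ncol(object),
                length(unique(as.character(
                    GenomicRanges::seqnames(
                        SummarizedExperiment::rowRanges(object)))))))
    d <- dosage(object)
    cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(d))))
})

#' BlupFit: REML fit of the two-random-effect trait model
#'
#' Result of \code{\link{fitBlup}} for the model
#' \eqn{y = \mu + u_{sample} + u_{rep} + e} with independent Gaussian
#' random effects.  The reported per-sample trait is \eqn{\mu + \hat
#' u_i} so downstream effect sizes stay on the measurement scale (mg/g).
#'
#' @slot blup Named numeric, \eqn{\mu +} predicted sample effect.
#' @slot varcomp Named numeric: \code{sample}, \code{rep},
#'   \code{residual} variance components (all \eqn{\ge 0}).
#' @slot mu Numeric grand mean.
#' @slot converged Logical convergence flag from the REML optimizer.
#' @exportClass BlupFit
setClass("BlupFit", representation(blup = "numeric", varcomp = "numeric",
                                   mu = "numeric", converged = "logical"))

setValidity("BlupFit", function(object) {
    if (any(object@varcomp < 0)) return("variance components must be >= 0")
    if (!all(c("sample", "rep", "residual") %in% names(object@varcomp)))
        return("varcomp needs names sample/rep/residual")
    TRUE
})

#' @rdname blup
#' @export
setMethod("blup", "BlupFit", function(object) object@blup)

#' @rdname varComp
#' @export
setMethod("varComp", "BlupFit", function(object) object@varcomp)

setMethod("show", "BlupFit", function(object) {
    cat(sprintf("BlupFit: %d samples, mu = %.4g\n",
                length(object@blup), object@mu))
    vc <- object@varcomp
    cat(sprintf("  var components: sample %.4g, rep %.4g, residual %.4g\n",
                vc["sample"], vc["rep"], vc["residual"]))
    if (!object@converged) cat("  WARNING: REML did not converge\n")
})

#' CoexprModules: weighted co-expression modules with trait annotation
#'
#' @slot colors Named character; gene id -> module color, \code{"grey"}
#'   meaning unassigned.
#' @slot eigengenes Numeric matrix (samples x modules) of first-PC
#'   module summaries.
#' @slot stats \code{data.frame} with one row per module: \code{module},
#'   \code{size}, \code{r} (eigengene-trait Pearson correlation),
#'   \code{p}.
#' @slot power Numeric soft-thresholding power used for the adjacency.
#' @exportClass CoexprModules
setClass("CoexprModules", representation(colors = "character",
                                         eigengenes = "matrix",
                                         stats = "data.frame",
                                         power = "numeric"))

#' @rdname moduleColors
#' @export
setMethod("moduleColors", "CoexprModules", function(object) object@colors)

#' @rdname eigengenes
#' @export
setMethod("eigengenes", "CoexprModules", function(object) object@eigengenes)

setMethod("show", "CoexprModules", function(object) {
    tab <- table(object@colors)
    cat(sprintf("CoexprModules: %d modules over %d genes (%d grey)\n",
                sum(names(tab) != "grey"), length(object@colors),
                sum(object@colors == "grey")))
    if (nrow(object@stats)) {
        best <- object@stats[which.max(abs(object@stats$r)), ]
        cat(sprintf("  strongest module-trait correlation: %s r = %.3f (p = %.3g)\n",
                    best$module, best$r, best$p))
    }
})

#' GeneNetwork: thresholded Pearson correlation network
#'
#' Undirected graph over a node set; an edge is kept iff the two-sided
#' t-transform p-value of the pairwise Pearson correlation is at or
#' below the stored threshold.
#'
#' @slot nodes \code{data.frame}: \code{id}, \code{role}
#'   (\code{"candidate"} or \code{"enzyme"}), \code{connected} (has at
#'   least one edge).
#' @slot edges \code{data.frame}: \code{gene1}, \code{gene2}, \code{r},
#'   \code{p}; gene1 < gene2, no self edges.
#' @slot pMax Numeric p-value threshold the edges satisfy.
#' @exportClass GeneNetwork
setClass("GeneNetwork", representation(nodes = "data.frame",
                                       edges = "data.frame",
                                       pMax = "numeric"))

setValidity("GeneNetwork", function(object) {
    e <- object@edges
    if (nrow(e)) {
        if (any(e$gene1 == e$gene2)) return("self edges not allowed")
        if (any(e$p > object@pMax)) return("edge p exceeds threshold")
    }
    TRUE
})

#' @rdname edges
#' @export
setMethod("edges", "GeneNetwork", function(object) object@edges)

#' @rdname nodes
#' @export
setMethod("nodes", "GeneNetwork", function(object) object@nodes)

setMethod("show", "GeneNetwork", function(object) {
    cat(sprintf(
        "GeneNetwork (p <= %g): %d nodes (%d connected), %d edges\n",
        object@pMax, nrow(object@nodes), sum(object@nodes$connected),
        nrow(object@edges)))
})
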