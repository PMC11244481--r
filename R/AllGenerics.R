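#' @import methods
#' @importFrom stats as.dist coef cor cutree dist hclust ks.test lm mad
#'   median optimize pchisq pf pnorm prcomp pt qchisq qnorm rbeta rnorm
#'   runif sd setNames var
#' @importFrom utils read.delim write.table head tail
NULL

#' Genotype dosage matrix
#'
#' Extract the SNP-by-sample alt-allele dosage matrix (values 0, 1, 2 or
#' \code{NA}) from a \linkS4class{GenotypeData} object.
#'
#' @param x A \linkS4class{GenotypeData} object.
#' @return An integer matrix, SNPs in rows, samples in columns.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' SNP metadata table
#'
#' @param x A \linkS4class{GenotypeData} object.
#' @return A \code{data.frame} with columns \code{id}, \code{chrom},
#'   \code{pos} (1-based bp), \code{ref}, \code{alt}.
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' Per-sample BLUP trait values
#'
#' @param object A \linkS4class{BlupFit} object.
#' @return Named numeric vector of \eqn{\mu + \hat u_i}, one per sample,
#'   on the original trait scale.
#' @export
setGeneric("blup", function(object) standardGeneric("blup"))

#' Variance components of a mixed-model fit
#'
#' @param object A \linkS4class{BlupFit} object.
#' @return Named numeric vector \code{c(sample=, rep=, residual=)}.
#' @export
setGeneric("varComp", function(object) standardGeneric("varComp"))

#' Module membership of a co-expression analysis
#'
#' @param object A \linkS4class{CoexprModules} object.
#' @return Named character vector mapping gene id to module color
#'   (\code{"grey"} = unassigned).
#' @export
setGeneric("moduleColors", function(object) standardGeneric("moduleColors"))

#' Module eigengenes
#'
#' @param object A \linkS4class{CoexprModules} object.
#' @return Numeric matrix, samples in rows, one column per module.
#' @export
setGeneric("eigengenes", function(object) standardGeneric("eigengenes"))

#' Edge table of a correlation network
#'
#' @param object A \linkS4class{GeneNetwork} object.
#' @return A \code{data.frame} with columns \code{gene1}, \code{gene2},
#'   \code{r}, \code{p}.
#' @export
setGeneric("edges", function(object) standardGeneric("edges"))

#' Node table of a correlation network
#'
#' @param object A \linkS4class{GeneNetwork} object.
#' @return A \code{data.frame} with columns \code{id}, \code{role},
#'   \code{connected}.
#' @export
setGeneric("nodes", function(object) standardGeneric("nodes"))
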