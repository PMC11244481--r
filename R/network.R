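#' Build a thresholded Pearson correlation network
#'
#' All pairwise Pearson correlations within the node set are computed
#' on the expression matrix; an edge is kept iff the two-sided
#' t-transform p-value is at or below \code{pMax}.  Constant-expression
#' genes (undefined correlations) are flagged and excluded from edges
#' but kept in the node list; isolated nodes are retained with
#' \code{connected = FALSE}.
#'
#' @param expr Numeric matrix, genes x samples (\eqn{\ge 3} samples).
#' @param nodeIds Character vector of genes to include (must exist in
#'   \code{expr}).
#' @param pMax Edge p-value threshold.
#' @param roles Optional named character vector id -> role
#'   (\code{"candidate"} / \code{"enzyme"}); defaults to
#'   \code{"candidate"}.
#' @return A \linkS4class{GeneNetwork}.
#' @export
buildNetwork <- function(expr, nodeIds, pMax, roles = NULL) {
    stopifnot(all(nodeIds %in% rownames(expr)))
    if (ncol(expr) < 3L) stop("need >= 3 samples")
    nodeIds <- unique(nodeIds)
    e <- expr[nodeIds, , drop = FALSE]
    n <- ncol(e)
    sds <- apply(e, 1L, sd)
    constant <- sds == 0
    r <- suppressWarnings(cor(t(e)))
    m <- length(nodeIds)
    out <- list()
    for (i in seq_len(m - 1L)) {
        for (j in (i + 1L):m) {
            if (constant[i] || constant[j]) next
            rij <- r[i, j]
            p <- .corPvalue(rij, n)
            if (!is.na(p) && p <= pMax)
                out[[length(out) + 1L]] <-
                    data.frame(gene1 = nodeIds[i], gene2 = nodeIds[j],
                               r = rij, p = p, stringsAsFactors = FALSE)
        }
    }
    ed <- if (length(out)) do.call(rbind, out) else
        data.frame(gene1 = character(0), gene2 = character(0),
                   r = numeric(0), p = numeric(0),
                   stringsAsFactors = FALSE)
    if (is.null(roles)) roles <- setNames(rep("candidate", m), nodeIds)
    nd <- data.frame(id = nodeIds,
                     role = unname(roles[nodeIds]),
                     connected = nodeIds %in% c(ed$gene1, ed$gene2),
                     constant = constant,
                     stringsAsFactors = FALSE)
    methods::new("GeneNetwork", nodes = nd, edges = ed, pMax = pMax)
}

#' Confirm candidates and call the key candidate set
#'
#' A candidate gene is \emph{confirmed} when it keeps at least one edge
#' to a key-enzyme panel gene in the permissive network (p at or below
#' the first threshold, conventionally 0.05), and is a \emph{key
#' candidate} when such an edge still survives in the stringent network
#' (conventionally p at or below 1e-6).
#'
#' @param netConfirm \linkS4class{GeneNetwork} built at the permissive
#'   threshold.
#' @param netKey \linkS4class{GeneNetwork} built at the stringent
#'   threshold (same node set).
#' @param candidateIds,enzymeIds Character vectors partitioning the
#'   node set.
#' @return List: \code{confirmed}, \code{key} (character vectors).
#' @export
callCandidates <- function(netConfirm, netKey, candidateIds, enzymeIds) {
    if (length(enzymeIds) == 0L) stop("empty enzyme panel")
    linked <- function(net) {
        e <- edges(net)
        toEnzyme <- (e$gene1 %in% candidateIds & e$gene2 %in% enzymeIds) |
                    (e$gene2 %in% candidateIds & e$gene1 %in% enzymeIds)
        unique(c(e$gene1[toEnzyme], e$gene2[toEnzyme]))
    }
    conf <- intersect(candidateIds, linked(netConfirm))
    key <- intersect(conf, linked(netKey))
    list(confirmed = sort(conf), key = sort(key))
}

#' Compare co-expression networks across trait-level groups
#'
#' Samples are ranked by the trait (ties broken deterministically by
#' sample id); the top, middle and bottom \code{groupSize} samples form
#' the High / Mid / Low groups, and a correlation network is built per
#' group at \code{pMax}.  The summary reports, per group, node counts
#' under both conventions (genes with at least one edge, and all
#' genes), edge counts, and the genes/edges unique to the group.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param trait Named numeric trait over the samples.
#' @param nodeIds Genes to network (default: all rows).
#' @param groupSize Samples per group (default 14).
#' @param pMax Edge threshold (default 0.05).
#' @return List: \code{networks} (named list Low/Mid/High),
#'   \code{groups} (sample ids per group), \code{summary}
#'   (\code{data.frame}).
#' @export
groupNetworkComparison <- function(expr, trait, nodeIds = rownames(expr),
                                   groupSize = 14L, pMax = 0.05) {
    ids <- colnames(expr)
    stopifnot(all(ids %in% names(trait)))
    if (3L * groupSize > length(ids))
        stop("need at least 3 * groupSize samples")
    tv <- trait[ids]
    ord <- ids[order(tv, ids)]          # ascending; ties by sample id
    n <- length(ord)
    lowS <- ord[seq_len(groupSize)]
    highS <- ord[(n - groupSize + 1L):n]
    midStart <- (n - groupSize) %/% 2L + 1L
    midS <- ord[midStart:(midStart + groupSize - 1L)]
    groups <- list(Low = lowS, Mid = midS, High = highS)
    nets <- lapply(groups, function(s)
        buildNetwork(expr[, s, drop = FALSE], nodeIds, pMax))
    edgeKey <- function(net) {
        e <- edges(net)
        if (nrow(e) == 0L) return(character(0))
        paste(e$gene1, e$gene2, sep = "|")
    }
    connGenes <- lapply(nets, function(nt)
        nodes(nt)$id[nodes(nt)$connected])
    ek <- lapply(nets, edgeKey)
    summ <- data.frame(
        group = names(nets),
        nodesConnected = vapply(connGenes, length, integer(1)),
        nodesAll = vapply(nets, function(nt) nrow(nodes(nt)), integer(1)),
        edges = vapply(nets, function(nt) nrow(edges(nt)), integer(1)),
        uniqueGenes = vapply(names(nets), function(g)
            length(setdiff(connGenes[[g]],
                           unlist(connGenes[setdiff(names(nets), g)]))),
            integer(1)),
        uniqueEdges = vapply(names(nets), function(g)
            length(setdiff(ek[[g]],
                           unlist(ek[setdiff(names(nets), g)]))),
            integer(1)),
        stringsAsFactors = FALSE, row.names = NULL)
    list(networks = nets, groups = groups, summary = summ)
}

#' Serialize a network as edge-list TSV and GraphML
#'
#' @param net A \linkS4class{GeneNetwork}.
#' @param basePath Path prefix; writes \code{<basePath>.tsv} and
#'   \code{<basePath>.graphml}.
#' @return Character vector of the two paths, invisibly.
#' @export
writeNetwork <- function(net, basePath) {
    tsv <- paste0(basePath, ".tsv")
    gml <- paste0(basePath, ".graphml")
    writeFunnelTable(edges(net), tsv)
    g <- igraph::graph_from_data_frame(
        edges(net)[, c("gene1", "gene2", "r", "p")],
        directed = FALSE, vertices = nodes(net))
    igraph::write_graph(g, gml, format = "graphml")
    invisible(c(tsv, gml))
}
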