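#' Filter genes with excessive zero expression
#'
#' Removes genes whose expression is zero in strictly more than
#' \code{zeroFraction} of the samples (a gene at exactly the fraction
#' is retained).
#'
#' @param expr Numeric matrix, genes x samples.
#' @param zeroFraction Maximum tolerated zero fraction (default 0.70).
#' @return Filtered matrix; errors if nothing survives.
#' @export
filterExpression <- function(expr, zeroFraction = 0.70) {
    zf <- rowMeans(expr == 0)
    keep <- zf <= zeroFraction
    if (!any(keep)) stop("all genes removed by the zero filter")
    expr[keep, , drop = FALSE]
}

#' Detect and remove outlier samples by hierarchical clustering
#'
#' Average-linkage clustering on Euclidean distances between sample
#' expression profiles.  A sample is flagged when the height at which
#' its singleton leaf first merges exceeds median + \code{nMad} MAD of
#' all leaf merge heights.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param nMad Flagging multiplier: a sample is an outlier when its
#'   leaf merge height exceeds median + \code{nMad} x MAD.  The default
#'   8 is calibrated so homogeneous expression is essentially never
#'   flagged while genuine profile outliers (whose merge heights sit
#'   one to two orders of magnitude above the null spread) always are.
#' @param override Logical; flagging more than 20% of samples stops
#'   with an error unless \code{TRUE}.
#' @return List: \code{expr} (filtered matrix), \code{dropped},
#'   \code{retained} (sample ids), \code{heights} (named leaf merge
#'   heights).
#' @export
removeOutlierSamples <- function(expr, nMad = 8, override = FALSE) {
    n <- ncol(expr)
    ids <- colnames(expr)
    if (n <= 2L) {
        warning("too few samples for outlier detection; no-op")
        return(list(expr = expr, dropped = character(0), retained = ids,
                    heights = setNames(rep(NA_real_, n), ids)))
    }
    hc <- hclust(dist(t(expr)), method = "average")
    h <- rep(NA_real_, n)
    for (r in seq_len(nrow(hc$merge))) {
        for (s in 1:2) {
            m <- hc$merge[r, s]
            if (m < 0) h[-m] <- hc$height[r]
        }
    }
    names(h) <- ids
    cut <- median(h) + nMad * mad(h)
    flag <- h > cut & mad(h) > 0
    if (sum(flag) > 0.2 * n && !override)
        stop(sum(flag), " of ", n, " samples flagged as outliers (>20%); ",
             "rerun with override = TRUE to drop them")
    list(expr = expr[, !flag, drop = FALSE], dropped = ids[flag],
         retained = ids[!flag], heights = h)
}

#' Soft-thresholded correlation adjacency
#'
#' Unsigned weighted-network adjacency \eqn{a_{ij} = |cor(x_i,
#' x_j)|^\beta} (signed option: negative correlations mapped to 0 via
#' \eqn{((1+cor)/2)^\beta}).  Diagonal is 1; connectivity computations
#' exclude it.  Genes with zero variance get zero adjacency to
#' everything.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param power Soft-thresholding exponent \eqn{\beta}.
#' @param type \code{"unsigned"} (default) or \code{"signed"}.
#' @return Symmetric genes x genes adjacency matrix.
#' @export
softAdjacency <- function(expr, power, type = c("unsigned", "signed")) {
    type <- match.arg(type)
    r <- suppressWarnings(cor(t(expr)))
    r[is.na(r)] <- 0
    a <- if (type == "unsigned") abs(r)^power else ((1 + r) / 2)^power
    diag(a) <- 1
    (a + t(a)) / 2
}

#' Choose the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the adjacency and connectivities \eqn{k_i =
#' \sum_{j \ne i} a_{ij}} are computed; the scale-free fit is the
#' squared correlation of \eqn{\log_{10} p(k)} versus \eqn{\log_{10}
#' k} over \code{nBins} equal-width connectivity bins, negated when the
#' regression slope is positive (the conventional sign penalty).  The
#' chosen power is the smallest one whose signed \eqn{R^2} reaches
#' \code{r2Target}, else the argmax.
#'
#' @param expr Numeric matrix, genes x samples (at least 3 genes).
#' @param powers Candidate powers (default 1 to 20 in half steps).
#' @param r2Target Target signed fit (default 0.85).
#' @param nBins Connectivity histogram bins.
#' @return List: \code{powers}, \code{fitR2} (signed), \code{meanK},
#'   \code{power} (chosen), \code{reachedTarget}.
#' @export
pickSoftThreshold <- function(expr, powers = seq(1, 20, by = 0.5),
                              r2Target = 0.85, nBins = 10L) {
    if (nrow(expr) < 3L) stop("need >= 3 genes")
    r <- suppressWarnings(cor(t(expr)))
    r[is.na(r)] <- 0
    absr <- abs(r)
    diag(absr) <- 0
    fit <- meanK <- numeric(length(powers))
    for (i in seq_along(powers)) {
        a <- absr^powers[i]
        k <- rowSums(a)
        meanK[i] <- mean(k)
        fit[i] <- .scaleFreeFit(k, nBins)
    }
    reached <- fit >= r2Target
    chosen <- if (any(reached)) powers[which(reached)[1L]]
              else powers[which.max(fit)]
    list(powers = powers, fitR2 = fit, meanK = meanK, power = chosen,
         reachedTarget = any(reached))
}

## signed scale-free topology fit index over equal-width k bins
.scaleFreeFit <- function(k, nBins = 10L) {
    k <- k[k > 0]
    if (length(unique(k)) < 3L) return(0)
    br <- seq(min(k), max(k), length.out = nBins + 1L)
    bin <- cut(k, breaks = br, include.lowest = TRUE)
    dk <- tapply(k, bin, mean)
    pk <- tapply(k, bin, length) / length(k)
    ok <- !is.na(dk) & !is.na(pk) & pk > 0
    if (sum(ok) < 3L) return(0)
    lx <- log10(dk[ok]); ly <- log10(pk[ok])
    sl <- coef(lm(ly ~ lx))[2L]
    r2 <- suppressWarnings(cor(lx, ly)^2)
    if (is.na(r2)) return(0)
    -sign(sl) * r2
}

#' Topological overlap matrix
#'
#' \eqn{TOM_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 -
#' a_{ij})} with \eqn{\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}; \eqn{TOM_{ii} = 1}.
#'
#' @param adjacency Symmetric adjacency matrix with entries in [0, 1].
#' @return Symmetric TOM matrix, entries in [0, 1], unit diagonal.
#' @export
tomMatrix <- function(adjacency) {
    if (!isSymmetric(unname(adjacency), tol = 1e-12))
        stop("adjacency must be symmetric")
    a <- adjacency
    diag(a) <- 0
    L <- a %*% a
    k <- rowSums(a)
    denom <- outer(k, k, pmin) + 1 - a
    tom <- (L + a) / denom
    diag(tom) <- 1
    dimnames(tom) <- dimnames(adjacency)
    (tom + t(tom)) / 2
}

## standard module color ladder, by decreasing module size
.moduleColorLadder <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")

#' Detect co-expression modules from a TOM
#'
#' Average-linkage clustering on the dissimilarity \eqn{1 - TOM} with a
#' static tree cut: the dendrogram is cut at \code{cutHeight} (default
#' 0.995 of the maximum merge height) and every resulting branch with
#' fewer than \code{minModuleSize} genes is assigned to \code{"grey"}.
#' Color labels follow the conventional ladder by decreasing module
#' size.
#'
#' @param tom TOM matrix from \code{\link{tomMatrix}} (gene ids as
#'   dimnames).
#' @param minModuleSize Minimum genes per module (default 5).
#' @param cutHeight Static cut height; \code{NULL} = 0.995 max height.
#' @return Named character vector gene -> color.
#' @export
detectModules <- function(tom, minModuleSize = 5L, cutHeight = NULL) {
    dis <- 1 - tom
    hc <- hclust(as.dist(dis), method = "average")
    if (is.null(cutHeight)) cutHeight <- 0.995 * max(hc$height)
    cl <- cutree(hc, h = cutHeight)
    sizes <- table(cl)
    keep <- names(sizes)[sizes >= minModuleSize]
    colors <- setNames(rep("grey", length(cl)), rownames(tom))
    keep <- keep[order(-sizes[keep])]
    for (i in seq_along(keep)) {
        lab <- if (i <= length(.moduleColorLadder))
            .moduleColorLadder[i] else paste0("module", i)
        colors[cl == as.integer(keep[i])] <- lab
    }
    colors
}

#' Module eigengenes and module-trait correlation
#'
#' The eigengene of a module is the first principal component of its
#' standardized member expression (samples scored), with the sign fixed
#' so the eigengene correlates positively with the module's mean
#' expression profile; a single-gene module uses that gene's
#' standardized profile.  Each eigengene is correlated with the trait
#' (Pearson), with the p-value from \eqn{t = r \sqrt{(n-2)/(1-r^2)}}.
#'
#' @param colors Named gene -> module assignment from
#'   \code{\link{detectModules}}.
#' @param expr Numeric matrix, genes x samples (superset of the genes
#'   in \code{colors}).
#' @param trait Named numeric vector over the samples.
#' @param power Soft power recorded in the result object.
#' @return A \linkS4class{CoexprModules}.
#' @export
moduleTrait <- function(colors, expr, trait, power = NA_real_) {
    ids <- colnames(expr)
    stopifnot(all(ids %in% names(trait)))
    tv <- as.numeric(trait[ids])
    n <- length(tv)
    mods <- setdiff(unique(colors), "grey")
    eig <- matrix(NA_real_, n, length(mods),
                  dimnames = list(ids, mods))
    stats <- data.frame(module = mods, size = NA_integer_,
                        r = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE)
    for (i in seq_along(mods)) {
        g <- names(colors)[colors == mods[i]]
        e <- .moduleEigengene(expr[g, , drop = FALSE])
        eig[, i] <- e
        r <- suppressWarnings(cor(e, tv))
        stats$size[i] <- length(g)
        stats$r[i] <- r
        stats$p[i] <- .corPvalue(r, n)
    }
    methods::new("CoexprModules", colors = colors, eigengenes = eig,
                 stats = stats, power = power)
}

## first PC of standardized module expression, sign-anchored
.moduleEigengene <- function(mexpr) {
    sds <- apply(mexpr, 1L, sd)
    use <- sds > 0
    if (!any(use)) return(rep(0, ncol(mexpr)))
    Z <- t(scale(t(mexpr[use, , drop = FALSE])))   # genes x samples
    if (nrow(Z) == 1L) return(as.numeric(Z))
    pc <- prcomp(t(Z), center = FALSE, scale. = FALSE)
    e <- pc$x[, 1L]
    if (suppressWarnings(cor(e, colMeans(Z))) < 0) e <- -e
    as.numeric(e)
}

## two-sided p of a Pearson correlation via the t transform
.corPvalue <- function(r, n) {
    if (is.na(r)) return(NA_real_)
    r <- max(min(r, 1 - 1e-15), -1 + 1e-15)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
}

#' Hub genes of a module by intramodular connectivity
#'
#' Edges inside the module with adjacency strictly above
#' \code{weightMin} are kept; intramodular connectivity is the weighted
#' degree on that thresholded subgraph; the top \code{topK} genes by
#' connectivity (ties broken by gene id) are the hubs.
#'
#' @param moduleGenes Character vector of member gene ids.
#' @param adjacency Full adjacency matrix (gene ids as dimnames).
#' @param weightMin Edge weight threshold (default 0.4, strict).
#' @param topK Number of hubs (default 5; smaller modules return all
#'   members, ranked).
#' @return \code{data.frame}: \code{gene}, \code{connectivity}, ranked;
#'   zero rows (with a message) when no edge survives.
#' @export
selectHubs <- function(moduleGenes, adjacency, weightMin = 0.4,
                       topK = 5L) {
    a <- adjacency[moduleGenes, moduleGenes, drop = FALSE]
    diag(a) <- 0
    a[a <= weightMin] <- 0
    if (all(a == 0)) {
        message("no intramodular edge above weight ", weightMin)
        return(data.frame(gene = character(0), connectivity = numeric(0),
                          stringsAsFactors = FALSE))
    }
    k <- rowSums(a)
    ord <- order(-k, moduleGenes)
    res <- data.frame(gene = moduleGenes[ord], connectivity = k[ord],
                      stringsAsFactors = FALSE, row.names = NULL)
    head(res, topK)
}
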