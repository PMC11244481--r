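## equal-variance two-sample t, robust to zero-variance groups
.pooledT <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    df <- n1 + n2 - 2L
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
    d <- mean(x) - mean(y)
    if (sp2 == 0) {
        if (d == 0) return(list(t = 0, p = 1, df = df))
        return(list(t = sign(d) * Inf, p = 0, df = df))
    }
    tt <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
    list(t = tt, p = 2 * pt(-abs(tt), df), df = df)
}

.oneSampleT <- function(x, mu) {
    n <- length(x)
    s <- sd(x)
    d <- mean(x) - mu
    if (is.na(s) || s == 0) {
        if (d == 0) return(list(t = 0, p = 1))
        return(list(t = sign(d) * Inf, p = 0))
    }
    tt <- d / (s / sqrt(n))
    list(t = tt, p = 2 * pt(-abs(tt), n - 1L))
}

#' Genotype-group trait contrast and impact rate for one SNP
#'
#' Samples are split into the two homozygote dosage classes (0 and 2;
#' heterozygotes excluded by default, or pooled with the minor
#' homozygote via \code{poolHet}), compared with an equal-variance
#' two-sample t-test, and the impact rate computed as (high group mean
#' - low group mean) / low group mean x 100%, the "high" group being
#' the one with the larger mean (so the rate is never negative).
#'
#' @param genoAtSnp Named integer vector of dosages (0/1/2, NA allowed)
#'   for one SNP.
#' @param trait Named numeric trait values (mg/g) covering the samples.
#' @param poolHet Pool heterozygotes with the minor homozygote group.
#' @return List: \code{groupMeans} (named by dosage class), \code{n}
#'   per group, \code{t}, \code{p}, \code{impactRate} (%),
#'   \code{testable}.
#' @export
snpTraitTest <- function(genoAtSnp, trait, poolHet = FALSE) {
    ids <- names(genoAtSnp)
    stopifnot(!is.null(ids), all(ids %in% names(trait)))
    y <- as.numeric(trait[ids])
    g <- as.integer(genoAtSnp)
    ok <- !is.na(g) & !is.na(y)
    g <- g[ok]; y <- y[ok]
    gm <- tapply(y, factor(g, levels = 0:2), mean)
    n0 <- sum(g == 0); n2 <- sum(g == 2)
    if (poolHet) {
        minor <- if (n0 <= n2) 0L else 2L
        g[g == 1L] <- minor
    }
    a <- y[g == 0]; b <- y[g == 2]
    if (length(a) < 2L || length(b) < 2L)
        return(list(groupMeans = gm, n = c(`0` = length(a), `2` = length(b)),
                    t = NA_real_, p = NA_real_, impactRate = NA_real_,
                    testable = FALSE))
    tt <- .pooledT(a, b)
    hi <- max(mean(a), mean(b)); lo <- min(mean(a), mean(b))
    rate <- if (lo > 0) (hi - lo) / lo * 100 else NA_real_
    if (hi == lo) rate <- 0
    list(groupMeans = gm, n = c(`0` = length(a), `2` = length(b)),
         t = tt$t, p = tt$p, impactRate = rate, testable = TRUE)
}

#' Summarize significant SNP-trait associations
#'
#' Counts and percentages (100 x part / whole, rounded to one decimal)
#' of significant SNPs, of in-ORF versus out-of-ORF locations, and of
#' mutation-consequence classes.
#'
#' @param stats \code{data.frame} with at least column \code{p} (one
#'   row per SNP); optional logical \code{inOrf} and character
#'   \code{class} columns (as from \code{\link{classifyMutation}}).
#' @param alpha Significance level (default 0.05, uncorrected).
#' @return List: \code{nSnps}, \code{nSignificant}, \code{pctSignificant},
#'   and, when available, \code{inOrf} / \code{classCounts} /
#'   \code{classPct} computed over the significant in-ORF SNPs.
#' @export
significantSnpSummary <- function(stats, alpha = 0.05) {
    pct <- function(part, whole)
        if (whole > 0) round(100 * part / whole, 1) else 0
    sig <- !is.na(stats$p) & stats$p <= alpha
    out <- list(nSnps = nrow(stats), nSignificant = sum(sig),
                pctSignificant = pct(sum(sig), nrow(stats)))
    if ("inOrf" %in% names(stats)) {
        out$inOrf <- c(inside = sum(sig & stats$inOrf),
                       outside = sum(sig & !stats$inOrf))
    }
    if ("class" %in% names(stats)) {
        sub <- stats[sig & stats$class != "outside-ORF", , drop = FALSE]
        cc <- table(factor(sub$class,
                           levels = c("non-synonymous", "synonymous",
                                      "frameshift")))
        out$classCounts <- c(cc)
        out$classPct <- vapply(cc, pct, numeric(1), whole = nrow(sub))
    }
    out
}

#' Find the longest open reading frame in an mRNA sequence
#'
#' Scans the three forward frames of the given (already oriented, 5'
#' to 3') sequence for ATG-initiated, stop-terminated reading frames
#' and returns the longest one of at least \code{minLen} nucleotides
#' (stop codon included, coordinates 1-based inclusive); ties go to the
#' earliest start.  Codons containing N never match ATG or a stop.
#'
#' @param mrna Character string or \code{DNAString} over A/C/G/T/N.
#' @param minLen Minimum ORF length in nt, stop included (default 150).
#' @return List \code{(start, end, length)} or \code{NULL} when no
#'   qualifying ORF exists.
#' @export
findOrf <- function(mrna, minLen = 150L) {
    s <- toupper(as.character(mrna))
    if (grepl("[^ACGTN]", s)) stop("non-nucleotide characters in sequence")
    n <- nchar(s)
    best <- NULL
    stops <- c("TAA", "TAG", "TGA")
    for (f in 0:2) {
        if (n - 2L < 1L + f) next
        starts <- seq(1L + f, n - 2L, by = 3L)
        cod <- substring(s, starts, starts + 2L)
        atg <- which(cod == "ATG")
        stp <- which(cod %in% stops)
        if (length(atg) == 0L || length(stp) == 0L) next
        ## first in-frame stop at or after each ATG, vectorized
        nxt <- stp[findInterval(atg - 1L, stp) + 1L]
        ok <- !is.na(nxt)
        a <- atg[ok]; b <- nxt[ok]
        len <- (b - a + 1L) * 3L
        keep <- len >= minLen
        if (!any(keep)) next
        i <- which(keep)[order(-len[keep], a[keep])][1L]
        cand <- list(start = starts[a[i]], end = starts[b[i]] + 2L,
                     length = len[i])
        if (is.null(best) || cand$length > best$length ||
            (cand$length == best$length && cand$start < best$start))
            best <- cand
    }
    best
}

#' Classify the consequence of a variant within an mRNA
#'
#' A substitution inside the ORF is translated before and after
#' (standard genetic code): same amino acid gives \code{"synonymous"},
#' otherwise \code{"non-synonymous"} (stop gain/loss counts as
#' non-synonymous).  An insertion/deletion inside the ORF whose length
#' difference is not a multiple of 3 is a \code{"frameshift"}; an
#' in-frame InDel is classified \code{"non-synonymous"}.  Variants
#' outside the ORF (or in a transcript with no qualifying ORF) are
#' \code{"outside-ORF"}.
#'
#' @param mrna The transcript sequence (character or \code{DNAString}).
#' @param orf ORF coordinates from \code{\link{findOrf}} (may be
#'   \code{NULL}).
#' @param pos 1-based position of the variant within the mRNA (for
#'   InDels: position of the VCF-style anchor base).
#' @param ref,alt Reference and alternate alleles (strings).
#' @param gene Optional gene id carried through to the record.
#' @return List: \code{gene}, \code{pos}, \code{ref}, \code{alt},
#'   \code{inOrf}, \code{class}, and for ORF substitutions
#'   \code{aaBefore} / \code{aaAfter}.
#' @export
classifyMutation <- function(mrna, orf, pos, ref, alt,
                             gene = NA_character_) {
    s <- toupper(as.character(mrna))
    if (pos < 1L || pos + nchar(ref) - 1L > nchar(s))
        stop("variant position outside the sequence")
    if (substr(s, pos, pos + nchar(ref) - 1L) != toupper(ref))
        stop("ref allele does not match the sequence at pos ", pos)
    rec <- list(gene = gene, pos = pos, ref = ref, alt = alt,
                inOrf = FALSE, class = "outside-ORF",
                aaBefore = NA_character_, aaAfter = NA_character_)
    if (is.null(orf)) return(rec)
    inOrf <- pos >= orf$start && pos <= orf$end
    if (!inOrf) return(rec)
    rec$inOrf <- TRUE
    dlen <- abs(nchar(ref) - nchar(alt))
    if (dlen > 0L) {
        rec$class <- if (dlen %% 3L != 0L) "frameshift" else
            "non-synonymous"
        return(rec)
    }
    ## same-length substitution: translate the affected codon(s)
    off <- pos - orf$start
    ci <- off %/% 3L                      # first affected codon index
    cstart <- orf$start + 3L * ci
    span <- nchar(ref)
    cend <- orf$start + 3L * ((off + span - 1L) %/% 3L) + 2L
    before <- substr(s, cstart, cend)
    mut <- s
    substr(mut, pos, pos + span - 1L) <- toupper(alt)
    after <- substr(mut, cstart, cend)
    tr <- function(x) as.character(
        Biostrings::translate(Biostrings::DNAString(x),
                              if.fuzzy.codon = "X"))
    rec$aaBefore <- tr(before)
    rec$aaAfter <- tr(after)
    rec$class <- if (rec$aaBefore == rec$aaAfter) "synonymous" else
        "non-synonymous"
    rec
}

#' Seven-class genetic-effect (dominance) classification
#'
#' Labels are normalized so AA denotes the favorable homozygote (the
#' one with the larger trait mean).  Writing mid = (AA + GG)/2, the
#' heterozygote mean AG falls in exactly one class: AG > AA
#' over-dominant (OD); AG = AA complete dominant (CD); mid < AG < AA
#' incomplete dominant (ID); AG = mid additive (AD); GG < AG < mid
#' negative incomplete dominant (NID); AG = GG negative complete
#' dominant (NCD); AG < GG negative over-dominant (NOD).  Equalities
#' are decided outward from the midpoint by the chosen test: sample
#' means are never exactly equal, so \code{method = "ttest"} reads "="
#' as "not significantly different at \code{alpha}" (one-sample t of
#' the heterozygote values against the observed midpoint for AD;
#' two-sample equal-variance t against the relevant homozygote for
#' CD/NCD); \code{method = "exact"} uses arithmetic comparison with
#' tolerance \code{eps}.
#'
#' @param valHom1,valHet,valHom2 Trait values of the three genotype
#'   groups; all must be non-empty (a two-genotype SNP is an error).
#' @param alleles Length-2 character: the alleles of \code{valHom1} and
#'   \code{valHom2} homozygotes (used to name the favorable allele).
#' @param method \code{"ttest"} or \code{"exact"}.
#' @param alpha Equality significance level for \code{"ttest"}.
#' @param eps Equality tolerance for \code{"exact"}.
#' @return List: \code{means} (named AA/AG/GG after normalization),
#'   \code{favorableAllele}, \code{class}, \code{pHetVsFavorable}.
#' @export
classifyGeneticEffect <- function(valHom1, valHet, valHom2,
                                  alleles = c("A", "G"),
                                  method = c("ttest", "exact"),
                                  alpha = 0.05, eps = 1e-9) {
    method <- match.arg(method)
    if (length(valHom1) == 0L || length(valHet) == 0L ||
        length(valHom2) == 0L)
        stop("two-genotype SNP, effect analysis impossible")
    ## equality t-tests need replication in every group; singleton
    ## groups degrade to the arithmetic comparison
    if (method == "ttest" &&
        min(length(valHom1), length(valHet), length(valHom2)) < 2L)
        method <- "exact"
    ## normalize: AA = favorable homozygote (larger mean)
    if (mean(valHom1) >= mean(valHom2)) {
        aa <- valHom1; gg <- valHom2; fav <- alleles[1L]
    } else {
        aa <- valHom2; gg <- valHom1; fav <- alleles[2L]
    }
    mAA <- mean(aa); mGG <- mean(gg); mAG <- mean(valHet)
    mid <- (mAA + mGG) / 2
    eqMid <- if (method == "exact") abs(mAG - mid) <= eps else
        .oneSampleT(valHet, mid)$p >= alpha
    cls <- if (eqMid) "AD" else if (mAG > mid) {
        eqAA <- if (method == "exact") abs(mAG - mAA) <= eps else
            .pooledT(valHet, aa)$p >= alpha
        if (eqAA) "CD" else if (mAG > mAA) "OD" else "ID"
    } else {
        eqGG <- if (method == "exact") abs(mAG - mGG) <= eps else
            .pooledT(valHet, gg)$p >= alpha
        if (eqGG) "NCD" else if (mAG < mGG) "NOD" else "NID"
    }
    pHF <- if (length(valHet) > 1L && length(aa) > 1L)
        .pooledT(valHet, aa)$p else NA_real_
    list(means = c(AA = mAA, AG = mAG, GG = mGG),
         favorableAllele = fav, class = cls, pHetVsFavorable = pHF)
}
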