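#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF 4.x file and converts the GT field of every biallelic
#' record to an alt-allele dosage code (0, 1, 2; missing calls such as
#' \code{./.} become \code{NA}).  Multiallelic records (a comma in ALT)
#' are skipped with a warning.  Positions are taken verbatim (1-based).
#' Records whose REF and ALT lengths differ are retained and flagged as
#' InDels in the SNP table; they are used only by the
#' mutation-consequence stage.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @return A \linkS4class{GenotypeData} object.  The \code{snpInfo}
#'   table gains a logical \code{indel} column.
#' @export
readVCF <- function(path) {
    if (!file.exists(path)) stop("VCF file not found: ", path)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                         dimnames = list(NULL, names(fix)))
    if (nrow(fix) == 0L) stop("empty VCF: no variant records")
    if (!"gt" %in% slotNames(v) || ncol(v@gt) < 2L)
        stop("VCF has no genotype (GT) columns")
    fmt <- v@gt[, 1L]
    if (!all(vapply(strsplit(fmt, ":", fixed = TRUE),
                    function(f) "GT" %in% f, logical(1))))
        stop("FORMAT field lacks GT")
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi))
        warning(sum(multi), " multiallelic record(s) skipped")
    keep <- !multi & !is.na(fix[, "ALT"])
    if (!any(keep)) stop("no biallelic records in VCF")
    gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
    ## vectorized GT -> dosage via lookup over the few distinct GT strings
    g <- gsub("|", "/", as.vector(gt), fixed = TRUE)
    u <- unique(g)
    ucode <- vapply(strsplit(u, "/", fixed = TRUE), function(x) {
        if (length(x) == 0L || any(x == "." | is.na(x))) return(NA_integer_)
        sum(as.integer(x != "0"))
    }, integer(1))
    d <- matrix(ucode[match(g, u)], nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
    fix <- fix[keep, , drop = FALSE]
    ids <- fix[, "ID"]
    noid <- is.na(ids) | ids == "."
    ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
    rownames(d) <- ids
    gd <- GenotypeData(d, chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]),
                       ref = fix[, "REF"], alt = fix[, "ALT"])
    rr <- SummarizedExperiment::rowRanges(gd)
    S4Vectors::mcols(rr)$indel <-
        nchar(S4Vectors::mcols(rr)$ref) != nchar(S4Vectors::mcols(rr)$alt)
    SummarizedExperiment::rowRanges(gd) <- rr
    gd
}

#' Write a GenotypeData object to a VCF file
#'
#' Emits a minimal VCF 4.2 file with unphased GT calls (\code{0/0},
#' \code{0/1}, \code{1/1}, \code{./.}).  Round-tripping through
#' \code{\link{readVCF}} preserves sample order, positions and dosage
#' codes.
#'
#' @param gt A \linkS4class{GenotypeData} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeVCF <- function(gt, path) {
    info <- snpInfo(gt)
    d <- dosage(gt)
    gtcode <- c("0/0", "0/1", "1/1")
    body <- matrix("./.", nrow(d), ncol(d))
    ok <- !is.na(d)
    body[ok] <- gtcode[d[ok] + 1L]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", colnames(d)),
                       collapse = "\t")), con)
    lines <- paste(info$chrom, info$pos, info$id, info$ref, info$alt,
                   ".", ".", ".", "GT",
                   apply(body, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
    invisible(path)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' First column: gene/transcript id; header row: sample ids.  Values
#' must be non-negative normalized expression.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
readExpression <- function(path) {
    if (!file.exists(path)) stop("expression file not found: ", path)
    if (file.size(path) == 0L) stop("empty expression file")
    nf <- utils::count.fields(path, sep = "\t", quote = "")
    if (length(unique(nf)) != 1L)
        stop("ragged rows in expression file (unequal field counts)")
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("expression file needs >= 1 sample column")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate gene id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric expression values")
    if (any(m < 0, na.rm = TRUE)) stop("negative expression values")
    rownames(m) <- ids
    m
}

#' Write an expression matrix as TSV
#'
#' @param expr Numeric matrix, genes x samples.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(expr, path) {
    df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    writeFunnelTable(df, path)
}

#' Read replicated trait measurements
#'
#' Expects a TSV with columns \code{sample}, \code{rep}, \code{content}
#' (trait value, mg/g).  Every sample needs at least one record and all
#' contents must be non-negative.
#'
#' @param path Path to a tab-separated file.
#' @return \code{data.frame} with those three columns.
#' @export
readTraitTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample", "rep", "content")
    if (!all(need %in% names(df)))
        stop("trait table needs columns: ", paste(need, collapse = ", "))
    df <- df[, need]
    if (any(df$content < 0)) stop("trait content must be >= 0")
    df
}

#' Read gene models from a GFF3 file
#'
#' Imports \code{type == "gene"} records; 1-based inclusive coordinates
#' are preserved.  A light syntactic pre-check reports the first
#' malformed line (fewer than 9 tab-separated fields) by line number.
#'
#' @param path Path to a GFF3 file.
#' @return \code{GRanges}, names = gene ids (the \code{ID} attribute).
#' @export
readGFFGenes <- function(path) {
    ln <- readLines(path)
    dat <- !grepl("^#", ln) & nzchar(ln)
    nfield <- vapply(strsplit(ln[dat], "\t", fixed = TRUE), length,
                     integer(1))
    if (any(nfield != 9L)) {
        bad <- which(dat)[which(nfield != 9L)[1L]]
        stop(sprintf("malformed GFF3 line %d: expected 9 fields, got %d",
                     bad, nfield[which(nfield != 9L)[1L]]))
    }
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    if (length(gr) == 0L) stop("no gene records in GFF3")
    names(gr) <- gr$ID
    gr
}

#' Read a FASTA file into a DNAStringSet
#'
#' Sequence ids are truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return \code{DNAStringSet} named by id.
#' @export
readFastaSeqs <- function(path) {
    s <- Biostrings::readDNAStringSet(path)
    names(s) <- sub("\\s.*$", "", names(s))
    s
}

#' Write / read pipeline result tables (lossless TSV)
#'
#' All tabular stage outputs are written as tab-separated text with the
#' column order of the input data frame.  Doubles are serialized with 17
#' significant digits so a write-then-read round trip reproduces the
#' table exactly.
#'
#' @param df A \code{data.frame}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFunnelTable <- function(df, path) {
    out <- df
    for (j in seq_along(out)) {
        if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFunnelTable
#' @export
readFunnelTable <- function(path) {
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
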