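# Readers/writers for every on-disk format the pipeline touches.
#
# Methylation calls travel in a minimal VCF-style dialect: the usual "##"
# header lines plus a "#CHROM POS ID REF ALT QUAL FILTER INFO" column line;
# one data line per cytosine with POS 1-based, REF C (plus strand) or G
# (minus strand), and INFO "CS=<+|->;CC=<CG|CHG|CHH>;NM=<n_meth>;NU=<n_unmeth>".
# This dialect is self-contained and round-trippable; it does not claim
# compliance with full VCF 4.x (no genotype columns).

#' Read per-cytosine methylation calls from a VCF-style file
#'
#' Parses the methylation VCF dialect written by [writeMethylationVcf()].
#' Counts are parsed as non-negative integers and the methylation rate is
#' recomputed from the counts, never trusted from the file.
#'
#' @param path path to a methylation VCF-dialect file.
#' @return A [MethylationCalls-class] object sorted by (chrom, pos).
#' @examples
#' mc <- MethylationCalls("chr1", 101L, "+", "CG", 3L, 1L)
#' f <- tempfile(fileext = ".vcf")
#' writeMethylationVcf(mc, f)
#' identical(methRate(readMethylationVcf(f)), 0.75)
#' @export
readMethylationVcf <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    is_header <- startsWith(lines, "#")
    data <- lines[!is_header & nzchar(lines)]
    if (!length(data))
        return(MethylationCalls())
    line_no <- which(!is_header & nzchar(lines))
    fields <- strsplit(data, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 8L))
        stop("malformed VCF line ", line_no[which(nf < 8L)[1L]],
             ": expected 8 tab-separated columns")
    m <- matrix(unlist(lapply(fields, `[`, 1:8)), ncol = 8L, byrow = TRUE)
    pos <- suppressWarnings(as.integer(m[, 2L]))
    if (anyNA(pos))
        stop("malformed VCF line ", line_no[which(is.na(pos))[1L]],
             ": POS is not an integer")
    info <- m[, 8L]
    grab <- function(key) {
        v <- sub(paste0(".*(?:^|;)", key, "=([^;]*).*"), "\\1", info)
        bad <- !grepl(paste0("(^|;)", key, "="), info)
        if (any(bad))
            stop("malformed VCF line ", line_no[which(bad)[1L]],
                 ": INFO lacks ", key, "=")
        v
    }
    cs <- grab("CS"); cc <- grab("CC")
    nm <- suppressWarnings(as.integer(grab("NM")))
    nu <- suppressWarnings(as.integer(grab("NU")))
    if (anyNA(nm) || anyNA(nu))
        stop("malformed VCF line ",
             line_no[which(is.na(nm) | is.na(nu))[1L]],
             ": NM/NU counts are not integers")
    if (any(nm < 0L) || any(nu < 0L))
        stop("negative count on VCF line ", line_no[which(nm < 0L | nu < 0L)[1L]])
    bad_ctx <- !cc %in% .CONTEXTS
    if (any(bad_ctx))
        stop("malformed VCF line ", line_no[which(bad_ctx)[1L]],
             ": context '", cc[which(bad_ctx)[1L]], "'")
    MethylationCalls(m[, 1L], pos, cs, cc, nm, nu)
}

#' Write methylation calls in the VCF-style dialect
#'
#' @param calls a [MethylationCalls-class] object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMethylationVcf <- function(calls, path) {
    stopifnot(is(calls, "MethylationCalls"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2-methylation-dialect",
                 paste0("##INFO=<ID=CS,Type=Character,Description=",
                        "\"Strand of the cytosine\">"),
                 "##INFO=<ID=CC,Type=String,Description=\"Cytosine context\">",
                 "##INFO=<ID=NM,Type=Integer,Description=\"Methylated reads\">",
                 "##INFO=<ID=NU,Type=Integer,Description=\"Unmethylated reads\">",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (length(calls)) {
        std <- as.character(strand(calls))
        writeLines(paste(as.character(seqnames(calls)), start(calls), ".",
                         ifelse(std == "+", "C", "G"), ".", ".", "PASS",
                         sprintf("CS=%s;CC=%s;NM=%d;NU=%d", std,
                                 methContext(calls), nMeth(calls),
                                 nUnmeth(calls)),
                         sep = "\t"), con)
    }
    invisible(path)
}

#' Write per-position values as bedGraph
#'
#' Emits one line per position, \code{chrom<TAB>start<TAB>end<TAB>value} with
#' 0-based half-open coordinates (\code{start = pos - 1}) and values printed
#' with six decimals, ready for IGV or the UCSC genome browser.
#'
#' @param x a [MethylationCalls-class] (rates are written), a
#'   [GroupSummary-class] (pass \code{value} to pick a column), or a GRanges.
#' @param path output path.
#' @param value for GRanges-like input, the metadata column to write
#'   (default \code{"rate"}).
#' @return \code{path}, invisibly.
#' @export
writeBedGraph <- function(x, path, value = "rate") {
    vals <- mcols(x)[[value]]
    if (is.null(vals)) stop("no metadata column '", value, "'")
    if (anyNA(vals)) stop("undefined values cannot be written to bedGraph")
    if (length(x) &&
        !identical(order(as.factor(seqnames(x)), start(x)), seq_along(x)))
        stop("input must be sorted by (chrom, pos) for genome-browser use")
    con <- file(path, "w")
    on.exit(close(con))
    if (length(x))
        writeLines(paste(as.character(seqnames(x)), start(x) - 1L, end(x),
                         sprintf("%.6f", vals), sep = "\t"), con)
    invisible(path)
}

#' Read an annotation BED file
#'
#' Accepts BED 3/4/6.  Intervals are kept 0-based half-open internally (the
#' returned GRanges uses the usual 1-based closed convention, i.e.
#' \code{start(gr) == bedStart + 1}).  When the name column is absent, names
#' \code{region_<i>} are generated in file order.
#'
#' @param path path to a BED file.
#' @return a \code{GRanges} with a unique \code{name} metadata column.
#' @export
readBed <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- tryCatch(
        read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   colClasses = "character", quote = ""),
        error = function(e) {
            if (grepl("no lines available", conditionMessage(e)))
                data.frame()
            else stop(e)
        })
    if (!nrow(tab))
        return(GRanges(name = character()))
    if (ncol(tab) < 3L) stop("BED requires >= 3 columns")
    bstart <- as.integer(tab[[2L]]); bend <- as.integer(tab[[3L]])
    bad <- which(is.na(bstart) | is.na(bend) | bstart >= bend)
    if (length(bad))
        stop("invalid interval on BED line ", bad[1L],
             ": start must be < end (0-based half-open)")
    nm <- if (ncol(tab) >= 4L) tab[[4L]] else paste0("region_", seq_len(nrow(tab)))
    if (anyDuplicated(nm))
        stop("duplicate region name(s): ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    std <- if (ncol(tab) >= 6L) tab[[6L]] else "*"
    GRanges(tab[[1L]], IRanges(bstart + 1L, bend), strand = std, name = nm)
}

#' Write regions as BED
#'
#' For a [DMRSet-class], writes BED6 with name = the DMR identifier,
#' score = \code{-log10(q)} (capped at 1000), and strand \code{+} for hyper-
#' and \code{-} for hypomethylated regions (w.r.t. group 1).  For a plain
#' GRanges, writes BED4 using the \code{name} column.
#'
#' @param x a [DMRSet-class] or GRanges with a \code{name} column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(x, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(x)) {
        if (is(x, "DMRSet")) {
            mc <- mcols(x)
            score <- pmin(round(-log10(pmax(mc$q, 1e-300)), 4), 1000)
            writeLines(paste(as.character(seqnames(x)), start(x) - 1L, end(x),
                             mc$name, score,
                             ifelse(mc$direction == "hyper", "+", "-"),
                             sep = "\t"), con)
        } else {
            nm <- mcols(x)$name
            if (is.null(nm)) nm <- paste0("region_", seq_along(x))
            writeLines(paste(as.character(seqnames(x)), start(x) - 1L, end(x),
                             nm, sep = "\t"), con)
        }
    }
    invisible(path)
}

#' Read a gene expression table
#'
#' Tab-separated, one header line (\code{gene_id} then one column per
#' sample), one row per gene; values are non-negative expression levels in
#' whatever unit was supplied (TPM, FPKM, counts).
#'
#' @param path path to the TSV.
#' @return a numeric matrix, genes in rows, samples in columns.
#' @export
readExpressionTable <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      row.names = 1L)
    m <- as.matrix(tab)
    storage.mode(m) <- "double"
    if (any(m < 0, na.rm = TRUE)) stop("negative expression value in ", path)
    m
}

#' Read a DMR-gene association table
#'
#' Tab-separated with (at least) columns \code{dmr_id} and \code{gene_id};
#' a header line is detected and skipped if present.
#'
#' @param path path to the TSV.
#' @return a data.frame with columns \code{dmr_id}, \code{gene_id}.
#' @export
readPairTable <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    first <- readLines(path, n = 1L)
    hdr <- grepl("dmr_id", first, fixed = TRUE)
    tab <- read.table(path, sep = "\t", header = hdr,
                      colClasses = "character")
    if (!hdr) colnames(tab)[1:2] <- c("dmr_id", "gene_id")
    tab[, c("dmr_id", "gene_id")]
}
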