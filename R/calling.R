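# Per-cytosine methylation calling from bisulfite-aligned reads.
#
# Bisulfite treatment converts unmethylated cytosines to uracil (sequenced as
# T) and leaves methylated cytosines intact, so methylation is read out as
# C-vs-T at reference cytosines.  Reads derive from one of two converted
# strands: on the original-top (CT) strand forward-reference cytosines are
# informative (read base C = methylated, T = unmethylated); on the
# original-bottom (GA) strand the informative positions are reference Gs,
# i.e. cytosines of the reverse strand (read base G = methylated, A =
# unmethylated, in forward-reference orientation).

#' Options for methylation calling
#'
#' @param min_base_quality minimum phred base quality for a read base to be
#'   counted (default 20).
#' @param min_mapping_quality minimum mapping quality (default 10).
#' @param trim_ends number of bases ignored at each end of every read
#'   (default 0); a blunt guard against M-bias at read ends.
#' @param clip_overlap for properly paired reads whose mates overlap, count
#'   each fragment position once, taking the base of the mate with the higher
#'   base quality (ties go to read 1).  Default \code{TRUE}.
#' @param contexts subset of \code{c("CG","CHG","CHH")} to emit (default all).
#' @return a validated options list of class \code{CallingOptions}.
#' @export
CallingOptions <- function(min_base_quality = 20L, min_mapping_quality = 10L,
                           trim_ends = 0L, clip_overlap = TRUE,
                           contexts = .CONTEXTS) {
    stopifnot(min_base_quality >= 0, min_mapping_quality >= 0, trim_ends >= 0,
              is.logical(clip_overlap), all(contexts %in% .CONTEXTS),
              length(contexts) >= 1L)
    structure(list(min_base_quality = as.integer(min_base_quality),
                   min_mapping_quality = as.integer(min_mapping_quality),
                   trim_ends = as.integer(trim_ends),
                   clip_overlap = isTRUE(clip_overlap),
                   contexts = unique(contexts)),
              class = "CallingOptions")
}

#' Classify the trinucleotide context of a cytosine
#'
#' Looks at the two bases following the cytosine in reading direction:
#' \code{CG} if the next base is G; \code{CHG} if the next base is H
#' (A, C or T) and the one after is G; \code{CHH} otherwise.  For
#' minus-strand cytosines (a G on the forward reference) the two preceding
#' forward-strand bases are read complemented.  Returns \code{NA} when the
#' context cannot be determined (within two bases of the sequence end, or an
#' ambiguous base in the window).
#'
#' @param refseq reference sequence (character string or
#'   \code{\link[Biostrings]{DNAString}}).
#' @param pos 1-based position(s) of the cytosine (the C itself for strand
#'   \code{+}; the forward-strand G for strand \code{-}).
#' @param strand \code{"+"} or \code{"-"}, recycled along \code{pos}.
#' @return character vector of \code{"CG"}, \code{"CHG"}, \code{"CHH"} or
#'   \code{NA}.
#' @examples
#' classifyContext("ACGT", 2, "+")   # "CG"
#' classifyContext("ACAGT", 2, "+")  # "CHG"
#' classifyContext("ACATT", 2, "+")  # "CHH"
#' classifyContext("ACGT", 3, "-")   # "CG" (reverse-strand reading)
#' @export
classifyContext <- function(refseq, pos, strand = "+") {
    s <- toupper(as.character(refseq))
    n <- nchar(s)
    pos <- as.integer(pos)
    if (any(pos < 1L | pos > n))
        stop("position out of range [1, ", n, "]")
    strand <- rep_len(as.character(strand), length(pos))
    base0 <- substring(s, pos, pos)
    ok_base <- ifelse(strand == "+", base0 == "C", base0 == "G")
    if (!all(ok_base))
        stop("reference base at position ", pos[which(!ok_base)[1L]],
             " is not a cytosine on the requested strand")
    off1 <- ifelse(strand == "+", pos + 1L, pos - 1L)
    off2 <- ifelse(strand == "+", pos + 2L, pos - 2L)
    at <- function(p) ifelse(p >= 1L & p <= n, substring(s, p, p), "")
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    read1 <- at(off1); read2 <- at(off2)
    minus <- strand == "-"
    read1[minus] <- unname(comp[read1[minus]])
    read2[minus] <- unname(comp[read2[minus]])
    read1[is.na(read1)] <- ""; read2[is.na(read2)] <- ""
    out <- rep(NA_character_, length(pos))
    h <- c("A", "C", "T")
    out[read1 == "G"] <- "CG"
    out[read1 %in% h & read2 == "G"] <- "CHG"
    out[read1 %in% h & read2 %in% h] <- "CHH"
    out
}

# Expand M/=/X cigar blocks of a set of alignments into one row per aligned
# base: (read index, reference position, query position, base, phred).
.alignedBases <- function(gal, seqs, quals) {
    cig <- GenomicAlignments::cigar(gal)
    ops <- c("M", "=", "X")
    rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        cig, pos = BiocGenerics::start(gal), ops = ops)
    qr <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = ops)
    rrl <- unlist(rr); qrl <- unlist(qr)
    w <- width(rrl)
    ridx <- rep(rep(seq_along(cig), S4Vectors::elementNROWS(rr)), w)
    refpos <- sequence(w, from = start(rrl))
    qpos <- sequence(w, from = start(qrl))
    offs <- cumsum(as.numeric(Biostrings::width(seqs))) -
        as.numeric(Biostrings::width(seqs))
    gidx <- offs[ridx] + qpos
    bigseq <- as.character(unlist(seqs))
    bigqual <- as.character(unlist(quals))
    base <- substring(bigseq, gidx, gidx)
    qv <- as.integer(charToRaw(paste(substring(bigqual, gidx, gidx),
                                     collapse = ""))) - 33L
    data.table::data.table(read = ridx, refpos = refpos, qpos = qpos,
                           base = base, qual = qv)
}

# Bisulfite strand ("CT" or "GA") per alignment: honour an XG tag when the
# aligner wrote one, otherwise infer from orientation (directional protocol:
# forward read 1 / reverse read 2 sequence the original-top strand).
.bisulfiteStrand <- function(flag, xg) {
    paired <- bitwAnd(flag, 0x1L) > 0L
    rev <- bitwAnd(flag, 0x10L) > 0L
    first <- bitwAnd(flag, 0x40L) > 0L
    second <- bitwAnd(flag, 0x80L) > 0L
    inferred <- ifelse(!paired, ifelse(rev, "GA", "CT"),
                ifelse(first, ifelse(rev, "GA", "CT"),
                       ifelse(rev, "CT", "GA")))
    if (!is.null(xg)) {
        ok <- !is.na(xg) & xg %in% c("CT", "GA")
        inferred[ok] <- xg[ok]
    }
    inferred
}

# All cytosine positions (both strands) of one reference sequence within
# [lo, hi], with context; context-undeterminable positions are dropped.
.referenceCytosines <- function(seqstr, lo, hi) {
    lo <- max(1L, lo); hi <- min(nchar(seqstr), hi)
    if (hi < lo) return(data.table::data.table())
    win <- substring(seqstr, lo, hi)
    rel <- gregexpr("[CG]", win)[[1L]]
    if (rel[1L] == -1L) return(data.table::data.table())
    posv <- as.integer(rel) + lo - 1L
    basev <- substring(seqstr, posv, posv)
    stdv <- ifelse(basev == "C", "+", "-")
    ctx <- classifyContext(seqstr, posv, stdv)
    keep <- !is.na(ctx)
    data.table::data.table(refpos = posv[keep], cstrand = stdv[keep],
                           context = ctx[keep])
}

#' Call per-cytosine methylation from a bisulfite BAM
#'
#' Performs a strand-aware bisulfite pileup: for every reference cytosine
#' covered by at least one informative read base (in an emitted context), the
#' counts of methylation-supporting (unconverted C) and
#' non-methylation-supporting (converted C, read as T) bases are collected.
#' Forward-strand cytosines are counted from reads of the C-to-T converted
#' orientation, reverse-strand cytosines from the G-to-A orientation; other
#' read bases at the position are ignored.  Secondary, supplementary and
#' duplicate-flagged alignments are skipped; bases below the quality
#' thresholds, within \code{trim_ends} of a read end, or in the overlapping
#' portion of a properly-paired mate (when \code{clip_overlap}) are excluded.
#' Insertions contribute nothing to reference positions; deletions leave the
#' deleted positions uncovered; soft-clipped bases are ignored.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param reference reference genome: a FASTA path or a named
#'   \code{\link[Biostrings]{DNAStringSet}}.
#' @param options a [CallingOptions()] list.
#' @return a [MethylationCalls-class] object sorted by (chrom, pos).
#' @export
callMethylation <- function(bam, reference, options = CallingOptions()) {
    stopifnot(inherits(options, "CallingOptions"))
    ref <- if (is.character(reference))
        Biostrings::readDNAStringSet(reference) else reference
    names(ref) <- sub("\\s.*$", "", names(ref))
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam)))
        stop("missing BAM index (.bai) for ", bam,
             "; sort and index the file first")
    hdr <- Rsamtools::scanBamHeader(bam)[[1L]]
    so <- unname(sub(".*SO:", "",
                     grep("SO:", unlist(hdr$text["@HD"]), value = TRUE)))
    if (length(so) && !identical(so, "coordinate"))
        stop("BAM is not coordinate-sorted (SO:", so, ")")
    bam_contigs <- names(hdr$targets)
    unknown <- setdiff(bam_contigs, names(ref))
    if (length(unknown))
        stop("contig(s) absent from the reference: ",
             paste(unknown, collapse = ", "))
    flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE,
                                    isDuplicate = FALSE)
    param <- Rsamtools::ScanBamParam(
        flag = flags, what = c("qname", "flag", "mapq", "seq", "qual"),
        tag = "XG")
    gal <- GenomicAlignments::readGAlignments(bam, param = param)
    md <- mcols(gal)
    keep <- is.na(md$mapq) | md$mapq >= options$min_mapping_quality
    gal <- gal[keep]; md <- md[keep, ]
    if (!length(gal)) return(MethylationCalls())

    bt <- .alignedBases(gal, md$seq, md$qual)
    bt[, `:=`(chrom = as.character(GenomeInfoDb::seqnames(gal))[read],
              qname = md$qname[read],
              bs = .bisulfiteStrand(md$flag, md$tag.XG)[read],
              proper = bitwAnd(md$flag, 0x2L)[read] > 0L,
              first = bitwAnd(md$flag, 0x40L)[read] > 0L,
              rlen = GenomicAlignments::qwidth(gal)[read])]
    bt <- bt[qual >= options$min_base_quality]
    if (options$trim_ends > 0L)
        bt <- bt[qpos > options$trim_ends & qpos <= rlen - options$trim_ends]
    if (options$clip_overlap && nrow(bt)) {
        data.table::setorder(bt, chrom, refpos, qname, -qual, -first)
        dupmate <- bt$proper & duplicated(bt[, list(chrom, refpos, qname)])
        bt <- bt[!dupmate]
    }
    if (!nrow(bt)) return(MethylationCalls())

    out <- list()
    for (chr in unique(bt$chrom)) {
        seqstr <- toupper(as.character(ref[[chr]]))
        sub <- bt[chrom == chr]
        cyt <- .referenceCytosines(seqstr, min(sub$refpos), max(sub$refpos))
        if (!nrow(cyt)) next
        cyt <- cyt[context %in% options$contexts]
        if (!nrow(cyt)) next
        j <- sub[cyt, on = "refpos", nomatch = 0L, allow.cartesian = TRUE]
        j <- j[(cstrand == "+" & bs == "CT") | (cstrand == "-" & bs == "GA")]
        if (!nrow(j)) next
        j[, meth := (cstrand == "+" & base == "C") |
                    (cstrand == "-" & base == "G")]
        j[, unmeth := (cstrand == "+" & base == "T") |
                      (cstrand == "-" & base == "A")]
        agg <- j[meth | unmeth,
                 list(n_meth = sum(meth), n_unmeth = sum(unmeth)),
                 by = list(refpos, cstrand, context)]
        if (nrow(agg))
            out[[chr]] <- data.table::data.table(chrom = chr, agg)
    }
    if (!length(out)) return(MethylationCalls())
    res <- data.table::rbindlist(out)
    MethylationCalls(res$chrom, res$refpos, res$cstrand, res$context,
                     res$n_meth, res$n_unmeth)
}

#' Alignment quality statistics
#'
#' Summarizes a BAM file the way one inspects a fresh bisulfite alignment:
#' how many reads mapped, how many proper pairs, how often reads align to
#' multiple places, and the mismatch rate of the alignments.
#'
#' @param bam path to a BAM file.
#' @return an object of class \code{MappingStats}: a list with
#'   \code{n_reads_total} (primary records, mapped or not), \code{n_mapped},
#'   \code{n_pairs_mapped} (properly paired reads / 2),
#'   \code{fraction_mapped} (0, flagged via \code{empty = TRUE}, for an empty
#'   file), \code{multiplicity_histogram} (table of alignments per distinct
#'   read, secondary alignments included) and \code{mean_error_rate}
#'   (sum of aligner mismatch counts over aligned M/=/X bases; reads lacking
#'   the NM tag are excluded from both numerator and denominator).
#' @export
mappingStatistics <- function(bam) {
    param <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "cigar"), tag = "NM",
        flag = Rsamtools::scanBamFlag(isSupplementaryAlignment = FALSE))
    rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
    flag <- rec$flag
    n_rec <- length(flag)
    secondary <- bitwAnd(flag, 0x100L) > 0L
    unmapped <- bitwAnd(flag, 0x4L) > 0L
    proper <- bitwAnd(flag, 0x2L) > 0L
    primary <- !secondary
    n_total <- sum(primary)
    n_mapped <- sum(primary & !unmapped)
    n_pairs <- sum(primary & proper & !unmapped) %/% 2L
    # one multiplicity entry per distinct (read, mate) among mapped records
    mate <- ifelse(bitwAnd(flag, 0x80L) > 0L, "/2", "/1")
    key <- paste0(rec$qname, mate)[!unmapped]
    mult <- if (length(key)) table(table(key)) else table(integer())
    nm <- rec$tag$NM
    has_nm <- primary & !unmapped & !is.na(nm)
    aligned <- if (any(has_nm)) {
        optab <- GenomicAlignments::cigarOpTable(rec$cigar[has_nm])
        sum(optab[, c("M", "=", "X")])
    } else 0L
    err <- if (aligned > 0L) sum(nm[has_nm]) / aligned else 0
    structure(list(n_reads_total = n_total, n_mapped = n_mapped,
                   n_pairs_mapped = n_pairs,
                   fraction_mapped = if (n_total > 0L) n_mapped / n_total else 0,
                   multiplicity_histogram = mult,
                   mean_error_rate = err,
                   empty = n_rec == 0L),
              class = "MappingStats")
}

#' @export
print.MappingStats <- function(x, ...) {
    cat("MappingStats\n")
    cat("  reads total:   ", x$n_reads_total, "\n")
    cat("  reads mapped:  ", x$n_mapped,
        sprintf(" (%.1f%%)", 100 * x$fraction_mapped), "\n")
    cat("  proper pairs:  ", x$n_pairs_mapped, "\n")
    cat("  mean error rate:", signif(x$mean_error_rate, 4), "\n")
    if (x$empty) cat("  [empty file]\n")
    invisible(x)
}
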