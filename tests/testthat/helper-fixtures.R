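# Fixture builders and independent oracles used across the suite.
# Oracles are written as plain loops, deliberately sharing no code with the
# package implementation they check.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

# --- SAM fixture -> sorted indexed BAM --------------------------------------

# records: data.frame with qname, flag, chrom, pos, mapq, cigar, seq, qual
# (phred string), and optional tags (character, e.g. "NM:i:0\tXG:Z:CT").
# mate fields (rnext/pnext/tlen) filled as unpaired unless given.
fixture_bam <- function(records, seqs, dir = tempfile("bamfix")) {
    dir.create(dir, showWarnings = FALSE)
    sam <- file.path(dir, "fix.sam")
    con <- file(sam, "w")
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 paste0("@SQ\tSN:", names(seqs), "\tLN:", nchar(seqs))), con)
    for (i in seq_len(nrow(records))) {
        r <- records[i, ]
        line <- paste(r$qname, r$flag, r$chrom, r$pos, r$mapq, r$cigar,
                      if (!is.null(r$rnext)) r$rnext else "*",
                      if (!is.null(r$pnext)) r$pnext else 0,
                      if (!is.null(r$tlen)) r$tlen else 0,
                      r$seq, r$qual, sep = "\t")
        if (!is.null(r$tags) && nzchar(r$tags))
            line <- paste(line, r$tags, sep = "\t")
        writeLines(line, con)
    }
    close(con)
    samToSortedIndexedBam(sam, file.path(dir, "fix.bam"))
}

# --- independent brute-force bisulfite pileup -------------------------------

# Enumerates every aligned base of every record by walking the cigar one
# operation at a time, applies the calling rules (quality, trim, overlap
# clip by higher quality then read 1), and tallies counts per reference
# cytosine.  Returns data.frame(chrom, pos, strand, context, n_meth,
# n_unmeth) sorted by (chrom, pos).
brute_pileup <- function(records, seqs, min_bq = 20, min_mq = 10,
                         trim_ends = 0, clip_overlap = TRUE,
                         contexts = c("CG", "CHG", "CHH")) {
    rows <- list()
    for (i in seq_len(nrow(records))) {
        r <- records[i, ]
        flag <- r$flag
        if (bitwAnd(flag, 0x4) > 0 || bitwAnd(flag, 0x100) > 0 ||
            bitwAnd(flag, 0x800) > 0 || bitwAnd(flag, 0x400) > 0) next
        if (r$mapq < min_mq) next
        xg <- if (!is.null(r$tags) && grepl("XG:Z:", r$tags))
            sub(".*XG:Z:(\\w+).*", "\\1", r$tags) else NA
        if (is.na(xg)) {
            paired <- bitwAnd(flag, 0x1) > 0
            rev <- bitwAnd(flag, 0x10) > 0
            first <- bitwAnd(flag, 0x40) > 0
            xg <- if (!paired) { if (rev) "GA" else "CT" }
                  else if (first) { if (rev) "GA" else "CT" }
                  else { if (rev) "CT" else "GA" }
        }
        ops <- regmatches(r$cigar, gregexpr("\\d+[MIDNSHP=X]", r$cigar))[[1]]
        refp <- r$pos; qp <- 1
        rl <- sum(as.integer(sub("[A-Z=]", "", ops[grepl("[MIS=X]", ops)])))
        sq <- strsplit(r$seq, "")[[1]]
        qv <- as.integer(charToRaw(r$qual)) - 33L
        for (op in ops) {
            n <- as.integer(sub("[A-Z=]", "", op))
            o <- sub("\\d+", "", op)
            if (o %in% c("M", "=", "X")) {
                for (k in 0:(n - 1)) {
                    rows[[length(rows) + 1]] <- list(
                        chrom = r$chrom, refpos = refp + k, base = sq[qp + k],
                        qual = qv[qp + k], qpos = qp + k, rlen = rl,
                        qname = r$qname, bs = xg,
                        proper = bitwAnd(flag, 0x2) > 0,
                        first = bitwAnd(flag, 0x40) > 0)
                }
                refp <- refp + n; qp <- qp + n
            } else if (o %in% c("I", "S")) qp <- qp + n
            else if (o %in% c("D", "N")) refp <- refp + n
        }
    }
    if (!length(rows)) return(data.frame())
    bt <- do.call(rbind, lapply(rows, as.data.frame))
    bt <- bt[bt$qual >= min_bq & bt$qpos > trim_ends &
             bt$qpos <= bt$rlen - trim_ends, ]
    if (clip_overlap && nrow(bt)) {
        bt <- bt[order(bt$chrom, bt$refpos, bt$qname, -bt$qual, -bt$first), ]
        dup <- bt$proper & duplicated(paste(bt$chrom, bt$refpos, bt$qname))
        bt <- bt[!dup, ]
    }
    out <- list()
    for (chr in unique(bt$chrom)) {
        s <- seqs[[chr]]
        chars <- strsplit(s, "")[[1]]
        n <- length(chars)
        for (p in seq_len(n)) {
            if (chars[p] == "C") { std <- "+" }
            else if (chars[p] == "G") { std <- "-" }
            else next
            ctx <- brute_context(chars, p, std)
            if (is.na(ctx) || !(ctx %in% contexts)) next
            sub_bt <- bt[bt$chrom == chr & bt$refpos == p &
                         bt$bs == (if (std == "+") "CT" else "GA"), ]
            if (!nrow(sub_bt)) next
            nm <- if (std == "+") sum(sub_bt$base == "C")
                  else sum(sub_bt$base == "G")
            nu <- if (std == "+") sum(sub_bt$base == "T")
                  else sum(sub_bt$base == "A")
            if (nm + nu == 0) next
            out[[length(out) + 1]] <- data.frame(
                chrom = chr, pos = p, strand = std, context = ctx,
                n_meth = nm, n_unmeth = nu)
        }
    }
    res <- do.call(rbind, out)
    if (is.null(res)) return(data.frame())
    res[order(res$chrom, res$pos), ]
}

brute_context <- function(chars, p, std) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    get <- function(i) if (i >= 1 && i <= length(chars)) chars[i] else ""
    if (std == "+") { b1 <- get(p + 1); b2 <- get(p + 2) }
    else { b1 <- unname(comp[get(p - 1)]); b2 <- unname(comp[get(p - 2)]) }
    b1[is.na(b1)] <- ""; b2[is.na(b2)] <- ""
    if (b1 == "G") return("CG")
    if (b1 %in% c("A", "C", "T")) {
        if (b2 == "G") return("CHG")
        if (b2 %in% c("A", "C", "T")) return("CHH")
    }
    NA_character_
}

calls_to_df <- function(calls) {
    data.frame(chrom = as.character(seqnames(calls)), pos = start(calls),
               strand = as.character(strand(calls)),
               context = methContext(calls),
               n_meth = nMeth(calls), n_unmeth = nUnmeth(calls))
}

# --- exhaustive Mann-Whitney oracle -----------------------------------------

# Full enumeration over all choose(n1+n2, n1) group assignments.
mwu_enum_p <- function(x, y) {
    n1 <- length(x); n2 <- length(y); n <- n1 + n2
    rk <- rank(c(x, y))
    U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combs <- combn(n, n1)
    Uall <- apply(combs, 2, function(idx) sum(rk[idx])) - n1 * (n1 + 1) / 2
    stat <- pmin(Uall, n1 * n2 - Uall)
    mean(stat <= min(U, n1 * n2 - U) + 1e-9)
}

# --- misc -------------------------------------------------------------------

qual_string <- function(q, len) paste(rep(rawToChar(as.raw(q + 33L)), len),
                                      collapse = "")

make_calls <- function(chrom, pos, strand, context, n_meth, n_unmeth)
    MethylationCalls(chrom, pos, strand, context, n_meth, n_unmeth)

# --- hand-constructed calling fixtures --------------------------------------

# A 60 bp reference with CpG, CHG and CHH sites on both strands.
fix_ref <- c(chrA = "ATACGTACGGTCCAGTTCACGTAGCATTACGGATCGTACCGGTTAACGTAGCTAGCGTAA")

sam_row <- function(qname, flag, pos, cigar, seq, qual, mapq = 60,
                    rnext = "*", pnext = 0, tlen = 0, tags = "") {
    data.frame(qname = qname, flag = flag, chrom = "chrA", pos = pos,
               mapq = mapq, cigar = cigar, seq = seq, qual = qual,
               rnext = rnext, pnext = pnext, tlen = tlen, tags = tags,
               stringsAsFactors = FALSE)
}

refsub <- function(from, to) substring(fix_ref[["chrA"]], from, to)

# Each fixture: list(records, note).  Sequences are derived from the
# reference, with deliberate conversions (C->T / G->A) and errors.
calling_fixtures <- function() {
    Q <- qual_string(40, 10)
    convert_ct <- function(s) gsub("C", "T", s)
    convert_ga <- function(s) gsub("G", "A", s)
    list(
        forward_unconverted = list(records = sam_row(
            "r1", 0, 2, "10M", refsub(2, 11), Q)),
        forward_converted = list(records = sam_row(
            "r2", 0, 2, "10M", convert_ct(refsub(2, 11)), Q)),
        reverse_strand_ga = list(records = rbind(
            sam_row("r3", 16, 2, "10M", refsub(2, 11), Q),
            sam_row("r4", 16, 2, "10M", convert_ga(refsub(2, 11)), Q))),
        overlapping_pair = list(records = rbind(
            # proper pair, mates overlap on 18..21; read 1 higher quality
            sam_row("p1", 99, 12, "10M", refsub(12, 21), qual_string(40, 10),
                    rnext = "=", pnext = 18, tlen = 16),
            sam_row("p1", 147, 18, "10M", convert_ct(refsub(18, 27)),
                    qual_string(30, 10), rnext = "=", pnext = 12,
                    tlen = -16))),
        indels_and_clips = list(records = rbind(
            sam_row("d1", 0, 2, "4M2D4M", paste0(refsub(2, 5), refsub(8, 11)),
                    qual_string(40, 8)),
            sam_row("i1", 0, 28, "4M2I4M",
                    paste0(refsub(28, 31), "TT", refsub(32, 35)),
                    qual_string(40, 10)),
            sam_row("s1", 0, 36, "2S6M", paste0("TT", refsub(36, 41)),
                    qual_string(40, 8)))),
        quality_and_flags = list(records = rbind(
            sam_row("q1", 0, 44, "10M", refsub(44, 53),
                    paste0(qual_string(40, 5), qual_string(10, 5))),
            sam_row("dup", 1024, 44, "10M", refsub(44, 53), Q),
            sam_row("sec", 256, 44, "10M", refsub(44, 53), Q)))
    )
}
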