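# Synthetic bisulfite data with known truth, for exercising and
# benchmarking every pipeline stage without external data.
#
# The count model is beta-binomial: per position and sample the coverage is
# Poisson and the methylated-read count is binomial with a beta-distributed
# success probability around the position's true rate, the standard
# overdispersed model for bisulfite counts (it has closed-form moments, so
# the generator itself is testable).  The default study shape mirrors a
# small case-control design: two groups of four samples, mean coverage 30.

#' Simulate a reference genome with controlled CpG density
#'
#' Background bases are drawn uniformly with every accidental CpG
#' dinucleotide destroyed, then CpG sites are planted by an independent
#' Bernoulli draw per position, so the realized CpG count is binomial with
#' a known expectation.  Deterministic given the seed.
#'
#' @param n_chrom number of chromosomes (default 1), named \code{chr1}, ...
#' @param length length of each chromosome in bp (>= 100).
#' @param cpg_density per-position probability of planting a CpG
#'   (default 0.01, a human-like genome average).
#' @param seed integer seed.
#' @return a list with \code{sequences} (named
#'   \code{\link[Biostrings]{DNAStringSet}}) and \code{cytosines}: a
#'   data.frame of every context-resolvable cytosine (chrom, pos, strand,
#'   context), consistent with [classifyContext()] by construction.
#' @export
simulateReference <- function(n_chrom = 1L, length = 10000L,
                              cpg_density = 0.01, seed = 1L) {
    stopifnot(length >= 100L, cpg_density >= 0, cpg_density < 0.5)
    set.seed(seed)
    seqs <- character(n_chrom)
    for (ci in seq_len(n_chrom)) {
        s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
        # destroy accidental CpGs (replacement cannot create new ones)
        cg <- which(s[-length] == "C" & s[-1L] == "G")
        if (base::length(cg))
            s[cg + 1L] <- sample(c("A", "T"), base::length(cg),
                                 replace = TRUE)
        if (cpg_density > 0) {
            sites <- which(runif(length - 1L) < cpg_density)
            if (base::length(sites) > 1L) {
                keep <- c(TRUE, diff(sites) > 1L)
                sites <- sites[keep]
            }
            s[sites] <- "C"; s[sites + 1L] <- "G"
        }
        seqs[ci] <- paste(s, collapse = "")
    }
    names(seqs) <- paste0("chr", seq_len(n_chrom))
    cyt <- do.call(rbind, lapply(names(seqs), function(chr) {
        d <- .referenceCytosines(seqs[[chr]], 1L, nchar(seqs[[chr]]))
        if (!nrow(d)) return(NULL)
        data.frame(chrom = chr, pos = d$refpos, strand = d$cstrand,
                   context = d$context)
    }))
    list(sequences = Biostrings::DNAStringSet(seqs),
         cytosines = cyt)
}

#' Plant differential methylation and generate per-position true rates
#'
#' Lays out the ground truth for a two-group comparison: non-overlapping
#' DMRs spanning a fixed number of consecutive CpG sites, with the two
#' groups' true rates at baseline +/- delta/2 (clamped to [0, 1]) inside a
#' DMR and identical outside.  Baseline CpG rates are bimodal
#' (Beta(0.3, 0.3)), the canonical shape of a methylome, except inside
#' planted DMRs where the baseline is intermediate (Beta(5, 5)), as real
#' DMRs concentrate in intermediately methylated regulatory regions.
#' Non-CpG cytosines get low rates (Beta(0.1, 1.9)).  Both strands of a
#' symmetric CpG share one true rate.
#'
#' @param reference output of [simulateReference()].
#' @param n_dmrs number of planted DMRs (default 20).
#' @param dmr_n_cpg CpG sites (forward-strand) per DMR (default 10).
#' @param delta true group mean difference inside DMRs, in [-1, 1]
#'   (default 0.5; the sign of each DMR's delta is randomized).
#' @param dispersion beta-binomial overdispersion rho in [0, 1)
#'   (default 0.05, typical for WGBS).
#' @param max_site_gap maximum spacing in bp between consecutive CpG sites
#'   of one planted DMR (default 300): planted regions are contiguous in
#'   CpG space, mirroring the CpG-dense regulatory context of real DMRs.
#' @param n_genes_linked,n_genes_unlinked expression genes associated with
#'   a planted DMR (alternating correlation sign) / independent genes.
#' @param seed integer seed.
#' @return a list of class \code{SimulationTruth}: \code{planted_dmrs}
#'   (data.frame chrom/start/end/delta, non-overlapping),
#'   \code{positions} (data.frame with per-position true rates
#'   \code{rate_g1}, \code{rate_g2}), \code{dispersion} and
#'   \code{expression_links} (data.frame dmr/gene/sign).
#' @export
simulateTruth <- function(reference, n_dmrs = 20L, dmr_n_cpg = 10L,
                          delta = 0.5, dispersion = 0.05,
                          max_site_gap = 300L,
                          n_genes_linked = min(n_dmrs, 10L),
                          n_genes_unlinked = 5L, seed = 1L) {
    stopifnot(abs(delta) <= 1, dispersion >= 0, dispersion < 1)
    set.seed(seed + 1L)
    cyt <- reference$cytosines
    cyt <- cyt[order(cyt$chrom, cyt$pos), ]
    # one true rate per CpG site, shared by the two symmetric strands:
    # key a CG by the forward position of its C
    site_pos <- ifelse(cyt$context == "CG" & cyt$strand == "-",
                       cyt$pos - 1L, cyt$pos)
    site_key <- paste0(cyt$chrom, ":", site_pos, ":", cyt$context)
    usite <- !duplicated(site_key)
    base_site <- numeric(sum(usite))
    is_cg <- cyt$context[usite] == "CG"
    base_site[is_cg] <- rbeta(sum(is_cg), 0.3, 0.3)
    base_site[!is_cg] <- rbeta(sum(!is_cg), 0.1, 1.9)
    base <- base_site[match(site_key, site_key[usite])]

    fwd_cg <- which(cyt$context == "CG" & cyt$strand == "+")
    dmrs <- NULL
    in_dmr <- rep(FALSE, nrow(cyt))
    dmr_delta <- rep(0, nrow(cyt))
    if (n_dmrs > 0L && length(fwd_cg) >= n_dmrs * dmr_n_cpg * 3L) {
        # candidate starts: dmr_n_cpg consecutive CpG sites on one
        # chromosome with inter-site spacing <= max_site_gap, so a planted
        # region is contiguous in the tested signal (real DMRs sit in
        # CpG-dense regulatory regions, not across CpG voids)
        cgpos <- cyt$pos[fwd_cg]; cgchr <- cyt$chrom[fwd_cg]
        nfc <- length(fwd_cg)
        gap_ok <- c(diff(cgpos) <= max_site_gap &
                    cgchr[-1L] == cgchr[-nfc], FALSE)
        # positions i where the next (dmr_n_cpg - 1) gaps are all small
        ok_start <- vapply(seq_len(nfc - dmr_n_cpg + 1L), function(i)
            all(gap_ok[i:(i + dmr_n_cpg - 2L)]), logical(1))
        starts <- which(ok_start)
        chosen <- integer()
        for (i in sample(starts)) {
            if (length(chosen) >= n_dmrs) break
            if (!length(chosen) ||
                all(abs(chosen - i) >= 3L * dmr_n_cpg))
                chosen <- c(chosen, i)
        }
        chosen <- sort(chosen)
        n_dmrs <- length(chosen)
        signs <- rep_len(c(1, -1), n_dmrs)[sample(n_dmrs)]
        dmrs <- data.frame(chrom = character(n_dmrs),
                           start = integer(n_dmrs), end = integer(n_dmrs),
                           delta = numeric(n_dmrs))
        for (k in seq_len(n_dmrs)) {
            sel <- fwd_cg[chosen[k]:(chosen[k] + dmr_n_cpg - 1L)]
            dmrs$chrom[k] <- cyt$chrom[sel[1L]]
            dmrs$start[k] <- cyt$pos[sel[1L]]
            dmrs$end[k] <- cyt$pos[sel[dmr_n_cpg]] + 1L  # include the G
            dmrs$delta[k] <- signs[k] * delta
            hit <- cyt$chrom == dmrs$chrom[k] &
                site_pos >= dmrs$start[k] & site_pos < dmrs$end[k] &
                cyt$context == "CG"
            in_dmr <- in_dmr | hit
            dmr_delta[hit] <- dmrs$delta[k]
            # intermediate baseline inside the DMR, shared across strands
            hs <- site_key[hit]
            bb <- rbeta(length(unique(hs)), 5, 5)
            base[hit] <- bb[match(hs, unique(hs))]
        }
        dmrs <- dmrs[dmrs$chrom != "", , drop = FALSE]
    }
    clamp <- function(x) pmin(1, pmax(0, x))
    pos <- data.frame(cyt, base_rate = base,
                      rate_g1 = clamp(base + dmr_delta / 2),
                      rate_g2 = clamp(base - dmr_delta / 2),
                      in_dmr = in_dmr)
    links <- NULL
    if (!is.null(dmrs) && nrow(dmrs) && n_genes_linked > 0L) {
        nl <- min(n_genes_linked, nrow(dmrs))
        links <- data.frame(dmr = seq_len(nl),
                            gene_id = sprintf("gene_%03d", seq_len(nl)),
                            sign = rep_len(c(-1, 1), nl))
    }
    unlinked <- if (n_genes_unlinked > 0L)
        sprintf("gene_u%02d", seq_len(n_genes_unlinked)) else character()
    structure(list(planted_dmrs = dmrs, positions = pos,
                   dispersion = dispersion, expression_links = links,
                   unlinked_genes = unlinked),
              class = "SimulationTruth")
}

# Beta-binomial draw: n_meth ~ BetaBin(cov, rate, rho).  rho = 0 collapses
# to plain binomial; rates of exactly 0/1 are deterministic.
.rbetabinom <- function(cov, rate, rho) {
    theta <- rate
    if (rho > 0) {
        mid <- rate > 0 & rate < 1
        a <- rate * (1 - rho) / rho
        b <- (1 - rate) * (1 - rho) / rho
        theta[mid] <- rbeta(sum(mid), a[mid], b[mid])
    }
    rbinom(length(cov), cov, theta)
}

#' Simulate per-sample methylation calls from planted truth
#'
#' Per position and sample, coverage is Poisson(\code{mean_coverage}) and
#' the methylated count is beta-binomial around the group's true rate with
#' overdispersion \code{truth$dispersion}.  Zero-coverage positions are
#' absent from the sample's calls (their rate is undefined).
#'
#' @param truth a [simulateTruth()] object.
#' @param n_per_group samples per group (default 4).
#' @param mean_coverage Poisson mean (default 30).
#' @param contexts cytosine contexts to simulate (default all three).
#' @param seed integer seed.
#' @return a named list of [MethylationCalls-class]: \code{S1..S<n>} form
#'   group 1 (control), \code{S<n+1>..S<2n>} group 2 (case).
#' @export
simulateCounts <- function(truth, n_per_group = 4L, mean_coverage = 30,
                           contexts = .CONTEXTS, seed = 1L) {
    stopifnot(inherits(truth, "SimulationTruth"), mean_coverage > 0)
    set.seed(seed + 2L)
    pos <- truth$positions[truth$positions$context %in% contexts, ]
    np <- nrow(pos)
    out <- list()
    for (s in seq_len(2L * n_per_group)) {
        rate <- if (s <= n_per_group) pos$rate_g1 else pos$rate_g2
        cov <- rpois(np, mean_coverage)
        nm <- .rbetabinom(cov, rate, truth$dispersion)
        keep <- cov > 0L
        out[[paste0("S", s)]] <- MethylationCalls(
            pos$chrom[keep], pos$pos[keep], pos$strand[keep],
            pos$context[keep], nm[keep], cov[keep] - nm[keep])
    }
    out
}

.revcomp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Simulate bisulfite paired-end reads as a sorted, indexed BAM
#'
#' Fragments are placed uniformly on the reference and assigned to the
#' original-top (CT) or original-bottom (GA) strand with equal probability.
#' Each informative cytosine of the fragment is methylated with its true
#' rate (sampled per fragment); unmethylated cytosines are converted
#' (C to T on the top strand, G to A in forward-reference orientation on
#' the bottom strand) with probability \code{conversion_rate}.  Sequencing
#' errors substitute random bases.  Reads carry correct flags, mate
#' information, NM mismatch tags and an XG bisulfite-strand tag.
#'
#' @param reference output of [simulateReference()].
#' @param truth a [simulateTruth()] object (supplies true rates; group 1
#'   rates are used).
#' @param n_fragments number of read pairs (default 2000).
#' @param read_length read length (default 100).
#' @param fragment_length outer fragment size (default 250).
#' @param error_rate per-base sequencing error probability (default 0).
#' @param conversion_rate bisulfite conversion probability for an
#'   unmethylated cytosine, in (0.9, 1] (default 1).
#' @param out output BAM path (without requiring the .bam suffix).
#' @param seed integer seed.
#' @return the path of the sorted, indexed BAM.
#' @export
simulateReads <- function(reference, truth, n_fragments = 2000L,
                          read_length = 100L, fragment_length = 250L,
                          error_rate = 0, conversion_rate = 1,
                          out = tempfile(fileext = ".bam"), seed = 1L) {
    stopifnot(conversion_rate > 0.9, conversion_rate <= 1,
              fragment_length >= read_length)
    set.seed(seed + 3L)
    seqs <- reference$sequences
    chrlens <- Biostrings::width(seqs)
    names(chrlens) <- names(seqs)
    pos <- truth$positions
    rate_of <- setNames(pos$rate_g1, paste0(pos$chrom, ":", pos$pos))
    sam <- tempfile(fileext = ".sam")
    con <- file(sam, "w")
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 paste0("@SQ\tSN:", names(seqs), "\tLN:", chrlens)), con)
    qual <- paste(rep("I", read_length), collapse = "")
    bases <- c("A", "C", "G", "T")
    for (f in seq_len(n_fragments)) {
        chr <- sample(names(seqs), 1L, prob = chrlens)
        fstart <- sample.int(chrlens[[chr]] - fragment_length + 1L, 1L)
        reffrag <- substring(as.character(seqs[[chr]]), fstart,
                             fstart + fragment_length - 1L)
        frag <- strsplit(reffrag, "")[[1L]]
        ot <- runif(1) < 0.5
        targets <- which(frag == (if (ot) "C" else "G"))
        if (length(targets)) {
            r <- rate_of[paste0(chr, ":", fstart + targets - 1L)]
            r[is.na(r)] <- 0
            meth <- runif(length(targets)) < r
            convert <- !meth & (runif(length(targets)) < conversion_rate)
            frag[targets[convert]] <- if (ot) "T" else "A"
        }
        if (error_rate > 0) {
            err <- which(runif(fragment_length) < error_rate)
            if (length(err))
                frag[err] <- vapply(frag[err], function(b)
                    sample(setdiff(bases, b), 1L), character(1))
        }
        fragstr <- paste(frag, collapse = "")
        seq_left <- substring(fragstr, 1L, read_length)
        seq_right <- substring(fragstr, fragment_length - read_length + 1L,
                               fragment_length)
        pos_left <- fstart
        pos_right <- fstart + fragment_length - read_length
        nm_of <- function(s, p) {
            refv <- strsplit(substring(as.character(seqs[[chr]]), p,
                                       p + read_length - 1L), "")[[1L]]
            sum(refv != strsplit(s, "")[[1L]])
        }
        nm_l <- nm_of(seq_left, pos_left); nm_r <- nm_of(seq_right, pos_right)
        cig <- paste0(read_length, "M")
        qn <- paste0("frag", f)
        xg <- if (ot) "CT" else "GA"
        tlen <- fragment_length
        if (ot) {
            # read 1 forward at fragment start, read 2 reverse at the end
            l1 <- paste(qn, 99L, chr, pos_left, 40L, cig, "=", pos_right,
                        tlen, seq_left, qual, paste0("NM:i:", nm_l),
                        paste0("XG:Z:", xg), sep = "\t")
            l2 <- paste(qn, 147L, chr, pos_right, 40L, cig, "=", pos_left,
                        -tlen, seq_right, qual, paste0("NM:i:", nm_r),
                        paste0("XG:Z:", xg), sep = "\t")
        } else {
            # bottom strand: read 1 reverse at the fragment end
            l1 <- paste(qn, 83L, chr, pos_right, 40L, cig, "=", pos_left,
                        -tlen, seq_right, qual, paste0("NM:i:", nm_r),
                        paste0("XG:Z:", xg), sep = "\t")
            l2 <- paste(qn, 163L, chr, pos_left, 40L, cig, "=", pos_right,
                        tlen, seq_left, qual, paste0("NM:i:", nm_l),
                        paste0("XG:Z:", xg), sep = "\t")
        }
        writeLines(c(l1, l2), con)
    }
    close(con)
    samToSortedIndexedBam(sam, out)
}

#' Convert a SAM file to a sorted, indexed BAM
#'
#' @param sam path to a SAM file.
#' @param out desired BAM path.
#' @return the BAM path, invisibly usable; the index sits next to it.
#' @export
samToSortedIndexedBam <- function(sam, out) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    tmp <- tempfile()
    bam0 <- Rsamtools::asBam(sam, tmp, overwrite = TRUE,
                             indexDestination = FALSE)
    sorted <- Rsamtools::sortBam(bam0, tempfile())
    file.copy(sorted, out, overwrite = TRUE)
    Rsamtools::indexBam(out)
    unlink(c(bam0, sorted))
    out
}

#' Simulate a gene expression table linked to planted DMRs
#'
#' Linked genes follow \code{a + b * (sample's mean methylation over the
#' DMR) + N(0, noise_sd)} with the link's sign carried by \code{b};
#' unlinked genes are independent of methylation.  Expression is clamped at
#' zero (a floor far below the working range, so correlations are
#' unaffected at the default scale).
#'
#' @param truth a [simulateTruth()] object with expression links.
#' @param mm a [MethylationMatrix-class] built from the simulated samples.
#' @param noise_sd Gaussian noise standard deviation (default 0.5;
#'   expression units are arbitrary, baseline 20, slope magnitude 10).
#' @param seed integer seed.
#' @return a numeric genes x samples matrix (see [readExpressionTable()]).
#' @export
simulateExpression <- function(truth, mm, noise_sd = 0.5, seed = 1L) {
    stopifnot(inherits(truth, "SimulationTruth"), is(mm, "MethylationMatrix"))
    set.seed(seed + 4L)
    links <- truth$expression_links
    if (is.null(links) || !nrow(links)) stop("truth carries no expression links")
    r <- methRate(mm)
    rr <- rowRanges(mm)
    genes <- c(links$gene_id, truth$unlinked_genes)
    em <- matrix(NA_real_, length(genes), ncol(mm),
                 dimnames = list(genes, colnames(mm)))
    for (k in seq_len(nrow(links))) {
        d <- truth$planted_dmrs[links$dmr[k], ]
        # both strand records of every CpG site inside [start, end]
        rows <- which(as.character(seqnames(rr)) == d$chrom &
                      start(rr) >= d$start & start(rr) <= d$end)
        meth <- colMeans(r[rows, , drop = FALSE], na.rm = TRUE)
        em[links$gene_id[k], ] <-
            pmax(0, 20 + links$sign[k] * 10 * meth +
                    rnorm(ncol(mm), sd = noise_sd))
    }
    for (g in truth$unlinked_genes)
        em[g, ] <- pmax(0, rnorm(ncol(mm), mean = 20, sd = 5))
    em
}

#' Simulate a complete case-control dataset
#'
#' One call that exercises the whole pipeline: reference, planted truth,
#' per-sample counts, the sample matrix, the group summary, expression and
#' DMR-gene pairs.  Defaults mirror a small WGBS case-control study: two
#' groups of four samples, mean coverage 30, 20 planted DMRs of 10 CpGs at
#' a true difference of 0.5.
#'
#' @param chrom_length reference length in bp (default 1e6).
#' @param cpg_density CpG planting probability (default 0.01).
#' @param n_dmrs,dmr_n_cpg,delta,dispersion passed to [simulateTruth()].
#' @param n_per_group,mean_coverage passed to [simulateCounts()].
#' @param min_coverage,min_samples matrix/summary thresholds (defaults 10, 3).
#' @param contexts contexts retained by the filtering stage (default
#'   \code{"CG"}, the standard DMR screen).
#' @param noise_sd expression noise (default 0.5).
#' @param seed integer seed driving every stage.
#' @return a list: \code{reference}, \code{truth}, \code{samples} (list of
#'   calls), \code{matrix}, \code{summary}, \code{group1}, \code{group2},
#'   \code{expression}, \code{pairs}.
#' @export
simulateCaseControl <- function(chrom_length = 1e6, cpg_density = 0.01,
                                n_dmrs = 20L, dmr_n_cpg = 10L, delta = 0.5,
                                dispersion = 0.05, n_per_group = 4L,
                                mean_coverage = 30, min_coverage = 10L,
                                min_samples = 3L, contexts = "CG",
                                noise_sd = 0.5, seed = 1L) {
    ref <- simulateReference(1L, as.integer(chrom_length), cpg_density, seed)
    truth <- simulateTruth(ref, n_dmrs = n_dmrs, dmr_n_cpg = dmr_n_cpg,
                           delta = delta, dispersion = dispersion,
                           seed = seed)
    samples <- simulateCounts(truth, n_per_group = n_per_group,
                              mean_coverage = mean_coverage, seed = seed)
    spec <- FilterSpec(min_coverage = min_coverage, contexts = contexts)
    filtered <- lapply(samples, function(x) filterCalls(x, spec)$calls)
    mm <- buildSampleMatrix(filtered, names(samples),
                            min_coverage = min_coverage)
    g1 <- names(samples)[seq_len(n_per_group)]
    g2 <- setdiff(names(samples), g1)
    gs <- summarizeGroups(mm, g1, g2, min_samples = min_samples)
    expr <- if (!is.null(truth$expression_links))
        simulateExpression(truth, mm, noise_sd = noise_sd, seed = seed)
        else NULL
    pairs <- if (!is.null(truth$expression_links))
        data.frame(dmr_id = paste0("planted_", truth$expression_links$dmr),
                   gene_id = truth$expression_links$gene_id)
        else NULL
    list(reference = ref, truth = truth, samples = filtered, matrix = mm,
         summary = gs, group1 = g1, group2 = g2, expression = expr,
         pairs = pairs)
}
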