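# Combining samples into groups: the per-position sample matrix, two-group
# summaries, and genome-wide overview statistics.

#' Build a positions-by-samples methylation matrix
#'
#' Takes per-sample methylation calls (paths to VCF-dialect files or
#' [MethylationCalls-class] objects), forms the union of their positions,
#' and records each sample's rate and coverage.  A sample's rate at a
#' position is set missing (\code{NA}) when its coverage is below
#' \code{min_coverage}; missingness is explicit because a rate of 0 is
#' biologically meaningful.
#'
#' @param samples list of [MethylationCalls-class] objects or file paths.
#' @param sample_names unique names, one per sample (defaults to list names).
#' @param min_coverage per-sample coverage below which the rate is treated
#'   as missing (default 10).
#' @return a [MethylationMatrix-class].
#' @export
buildSampleMatrix <- function(samples, sample_names = names(samples),
                              min_coverage = 10L) {
    if (is.null(sample_names) || length(sample_names) != length(samples))
        stop("one sample name per sample is required")
    if (anyDuplicated(sample_names))
        stop("duplicate sample names: ",
             paste(unique(sample_names[duplicated(sample_names)]),
                   collapse = ", "))
    calls <- lapply(samples, function(s)
        if (is.character(s)) readMethylationVcf(s) else s)
    dts <- lapply(seq_along(calls), function(i) {
        x <- calls[[i]]
        data.table::data.table(chrom = as.character(seqnames(x)),
                               pos = start(x),
                               std = as.character(strand(x)),
                               context = methContext(x),
                               rate = methRate(x),
                               cov = methCoverage(x),
                               sample = i)
    })
    all <- data.table::rbindlist(dts)
    if (!nrow(all)) {
        warning("no positions in any sample; empty matrix")
        se <- SummarizedExperiment(
            assays = list(rate = matrix(numeric(), 0L, length(samples),
                                        dimnames = list(NULL, sample_names)),
                          coverage = matrix(integer(), 0L, length(samples),
                                            dimnames = list(NULL, sample_names))),
            rowRanges = GRanges(context = character()))
        return(new("MethylationMatrix", se))
    }
    posn <- unique(all[, list(chrom, pos, std, context)])
    data.table::setorder(posn, chrom, pos)
    posn[, row := .I]
    all <- all[posn, on = c("chrom", "pos", "std", "context")]
    rate <- matrix(NA_real_, nrow(posn), length(samples),
                   dimnames = list(NULL, sample_names))
    cov <- matrix(0L, nrow(posn), length(samples),
                  dimnames = list(NULL, sample_names))
    idx <- cbind(all$row, all$sample)
    cov[idx] <- all$cov
    ok <- all$cov >= min_coverage
    rate[idx[ok, , drop = FALSE]] <- all$rate[ok]
    rr <- GRanges(posn$chrom, IRanges(posn$pos, width = 1L),
                  strand = posn$std, context = posn$context)
    se <- SummarizedExperiment(assays = list(rate = rate, coverage = cov),
                               rowRanges = rr)
    new("MethylationMatrix", se)
}

#' Two-group per-position summary
#'
#' Retains the positions where each group has at least \code{min_samples}
#' samples with sufficient coverage (i.e. a non-missing rate), and reports
#' the unweighted arithmetic mean rate per group plus their difference.
#' Swapping the two groups negates every difference exactly.
#'
#' @param mm a [MethylationMatrix-class].
#' @param group1,group2 disjoint character vectors of sample names.
#' @param min_samples minimum covered samples per group per position
#'   (default 1).
#' @return a [GroupSummary-class].
#' @export
summarizeGroups <- function(mm, group1, group2, min_samples = 1L) {
    stopifnot(is(mm, "MethylationMatrix"))
    if (!length(group1) || !length(group2)) stop("both groups must be nonempty")
    if (length(intersect(group1, group2))) stop("groups must be disjoint")
    missing_s <- setdiff(c(group1, group2), colnames(mm))
    if (length(missing_s))
        stop("unknown sample(s): ", paste(missing_s, collapse = ", "))
    if (min_samples > length(group1) || min_samples > length(group2))
        stop("min_samples exceeds a group size")
    r <- methRate(mm)
    r1 <- r[, group1, drop = FALSE]; r2 <- r[, group2, drop = FALSE]
    n1 <- rowSums(!is.na(r1)); n2 <- rowSums(!is.na(r2))
    keep <- n1 >= min_samples & n2 >= min_samples
    m1 <- rowMeans(r1, na.rm = TRUE)[keep]
    m2 <- rowMeans(r2, na.rm = TRUE)[keep]
    gr <- rowRanges(mm)[keep]
    mcols(gr) <- DataFrame(context = mcols(gr)$context,
                           mean_g1 = m1, mean_g2 = m2, diff = m1 - m2,
                           n_covered_g1 = as.integer(n1[keep]),
                           n_covered_g2 = as.integer(n2[keep]))
    new("GroupSummary", gr, group1 = as.character(group1),
        group2 = as.character(group2), minSamples = as.integer(min_samples))
}

# Euclidean distance over the positions where both samples have a rate;
# pairs sharing < 2 positions get NA.
.pairwiseSharedDist <- function(r) {
    n <- ncol(r)
    d <- matrix(0, n, n, dimnames = list(colnames(r), colnames(r)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        shared <- !is.na(r[, i]) & !is.na(r[, j])
        d[i, j] <- d[j, i] <-
            if (sum(shared) < 2L) NA_real_
            else sqrt(sum((r[shared, i] - r[shared, j])^2))
    }
    d
}

#' Genome-wide overview statistics for two groups
#'
#' The standard at-a-glance bundle: hierarchical clustering of the samples
#' (complete linkage on Euclidean distance over pairwise-shared non-missing
#' positions), binned group mean-rate distributions (width 0.1), per-group
#' boxplot five-number summaries, a 2-D density of (mean_g1, mean_g2), and
#' the histogram of per-position group differences (width 0.05).
#'
#' @param mm a [MethylationMatrix-class] with >= 2 samples.
#' @param gs the matching [GroupSummary-class].
#' @return a list with \code{hclust} (a \code{stats::hclust} tree; samples
#'   with no usable distance are excluded with a warning), \code{dist}
#'   (the full distance matrix), \code{rate_bins} (bin_lo, bin_hi, n_g1,
#'   n_g2), \code{boxplot} (per-group \code{fivenum}), \code{density2d}
#'   (\code{MASS::kde2d} of the two group means) and \code{diff_bins}.
#' @export
overviewStatistics <- function(mm, gs) {
    stopifnot(is(mm, "MethylationMatrix"), is(gs, "GroupSummary"))
    if (ncol(mm) < 2L) stop(">= 2 samples required for clustering")
    d <- .pairwiseSharedDist(methRate(mm))
    usable <- colSums(is.na(d)) == 0L
    if (!all(usable)) {
        warning("sample(s) excluded from clustering (too few shared ",
                "positions): ",
                paste(colnames(d)[!usable], collapse = ", "))
    }
    hc <- if (sum(usable) >= 2L)
        hclust(stats::as.dist(d[usable, usable, drop = FALSE]),
               method = "complete") else NULL
    m <- groupMeans(gs)
    brk10 <- (0:10) / 10
    bin10 <- function(x) pmin(findInterval(x, brk10, rightmost.closed = TRUE),
                              10L)
    rate_bins <- data.frame(
        bin_lo = brk10[-11L], bin_hi = brk10[-1L],
        n_g1 = as.integer(table(factor(bin10(m[, 1L]), levels = 1:10))),
        n_g2 = as.integer(table(factor(bin10(m[, 2L]), levels = 1:10))))
    brkd <- (-20:20) / 20
    bind <- function(x) pmin(findInterval(x, brkd, rightmost.closed = TRUE),
                             40L)
    diff_bins <- data.frame(
        bin_lo = brkd[-41L], bin_hi = brkd[-1L],
        n = as.integer(table(factor(bind(groupDiff(gs)), levels = 1:40))))
    dens <- if (length(gs) >= 2L &&
                (sd(m[, 1L]) > 0 || sd(m[, 2L]) > 0))
        MASS::kde2d(m[, 1L], m[, 2L], n = 50,
                    lims = c(0, 1, 0, 1)) else NULL
    list(hclust = hc, dist = d, rate_bins = rate_bins,
         boxplot = list(g1 = fivenum(m[, 1L]), g2 = fivenum(m[, 2L])),
         density2d = dens, diff_bins = diff_bins)
}

#' Genome-wide binned mean methylation per sample
#'
#' Tiles the genome into fixed-size bins and reports each sample's mean
#' rate per bin, a plain-text genome-wide methylation heatmap.  Only bins
#' containing at least one covered position for at least one sample are
#' emitted.
#'
#' @param mm a [MethylationMatrix-class].
#' @param bin_size bin width in bp (default 1e6).
#' @return a data.frame: chrom, bin_start (0-based), bin_end, then one mean
#'   column per sample (\code{NA} where the sample covers nothing in the
#'   bin).
#' @export
genomewideBinnedMeans <- function(mm, bin_size = 1e6) {
    stopifnot(is(mm, "MethylationMatrix"), bin_size >= 1)
    if (!nrow(mm))
        return(data.frame(chrom = character(), bin_start = numeric(),
                          bin_end = numeric()))
    r <- methRate(mm)
    dt <- data.table::data.table(
        chrom = as.character(seqnames(rowRanges(mm))),
        bin = (start(rowRanges(mm)) - 1L) %/% bin_size)
    vals <- data.table::data.table(dt, r)
    molten <- data.table::melt(vals, id.vars = c("chrom", "bin"),
                               variable.name = "sample", value.name = "rate",
                               variable.factor = FALSE)
    agg <- molten[!is.na(rate), list(mean_rate = mean(rate)),
                  by = list(chrom, bin, sample)]
    wide <- data.table::dcast(agg, chrom + bin ~ sample,
                              value.var = "mean_rate")
    data.table::setorder(wide, chrom, bin)
    res <- data.frame(chrom = wide$chrom,
                      bin_start = wide$bin * bin_size,
                      bin_end = (wide$bin + 1) * bin_size,
                      wide[, -(1:2)], check.names = FALSE)
    res
}
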