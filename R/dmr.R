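# DMR detection: recursive (circular-binary-style) segmentation of the
# per-position group methylation difference signal, with candidate regions
# scored by a two-sided Mann-Whitney U test and a two-sample two-dimensional
# Kolmogorov-Smirnov test, then Benjamini-Hochberg correction and filtering.
#
# On a linear difference signal the "circular" search over arcs is
# equivalent to searching all contiguous sub-intervals, which is what is
# implemented; the candidate at each recursion level is the sub-interval
# whose mean difference deviates most (in absolute value) from the mean of
# the current window.

#' Parameters for DMR calling
#'
#' @param max_gap maximum distance in bp between adjacent tested positions
#'   within one pre-segment (default 300).
#' @param min_cpg minimum tested positions per candidate region (default 10;
#'   must be >= 2).
#' @param min_diff minimum absolute mean methylation difference for a
#'   reported DMR (default 0.1).
#' @param max_q Benjamini-Hochberg q-value cutoff (default 0.05).
#' @param min_length_nt optional minimum DMR length in nucleotides.
#' @return a list of class \code{SegmentationParams}.
#' @export
SegmentationParams <- function(max_gap = 300L, min_cpg = 10L,
                               min_diff = 0.1, max_q = 0.05,
                               min_length_nt = NULL) {
    stopifnot(max_gap > 0, min_cpg >= 2, min_diff >= 0, max_q > 0,
              is.null(min_length_nt) || min_length_nt > 0)
    structure(list(max_gap = as.integer(max_gap), min_cpg = as.integer(min_cpg),
                   min_diff = min_diff, max_q = max_q,
                   min_length_nt = min_length_nt),
              class = "SegmentationParams")
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-based two-sample location test.  For combined sample sizes up to 20
#' the p-value is exact, by enumeration of all \code{choose(n1+n2, n1)}
#' assignments of the pooled observations to the two groups (extremeness
#' measured by \code{min(U, n1*n2 - U)}, which handles ties correctly);
#' beyond that, a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y numeric vectors.
#' @param exact_max maximum combined size for exact enumeration (default 20).
#' @return a list with \code{U} (statistic for \code{x}), \code{p}
#'   (two-sided, in (0, 1]) and \code{method} ("exact" or "normal").
#' @examples
#' mannWhitneyU(c(0.1, 0.2, 0.3, 0.4), c(0.6, 0.7, 0.8, 0.9))$p  # 2/70
#' @export
mannWhitneyU <- function(x, y, exact_max = 20L) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    n1 <- length(x); n2 <- length(y); n <- n1 + n2
    if (n1 == 0L || n2 == 0L) stop("both samples must be nonempty")
    rk <- rank(c(x, y))
    U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    if (n <= exact_max) {
        p <- .mwuExactP(rk, n1, n2, U)
        return(list(U = U, p = p, method = "exact"))
    }
    mu <- n1 * n2 / 2
    tie_tab <- table(rk)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    list(U = U, p = min(1, 2 * pnorm(-z)), method = "normal")
}

# Exact two-sided MWU p-value over all choose(n1+n2, n1) group assignments
# of the pooled observations, ties included.  Counts assignments by rank
# sum with a subset-sum dynamic program over the (doubled, hence integer)
# midranks -- equivalent to full enumeration, feasible at any n used here.
.mwuExactP <- function(rk, n1, n2, U_obs) {
    n <- n1 + n2
    w <- as.integer(round(2 * rk))
    S <- sum(w)
    # cnt[k + 1, s + 1] = number of k-subsets with doubled rank sum s
    cnt <- matrix(0, n1 + 1L, S + 1L)
    cnt[1L, 1L] <- 1
    for (x in w) {
        kmax <- n1
        for (k in kmax:1L) {
            src <- cnt[k, 1:(S + 1L - x)]
            cnt[k + 1L, (x + 1L):(S + 1L)] <-
                cnt[k + 1L, (x + 1L):(S + 1L)] + src
        }
    }
    s_vals <- which(cnt[n1 + 1L, ] > 0) - 1L
    counts <- cnt[n1 + 1L, s_vals + 1L]
    U_all <- s_vals / 2 - n1 * (n1 + 1) / 2
    stat <- pmin(U_all, n1 * n2 - U_all)
    obs <- min(U_obs, n1 * n2 - U_obs)
    sum(counts[stat <= obs + 1e-9]) / choose(n, n1)
}

# Kolmogorov-Smirnov tail probability Q_KS(lambda) = 2 sum (-1)^(j-1) e^(-2 j^2 lambda^2)
.qks <- function(lambda) {
    if (lambda < 1e-3) return(1)
    j <- 1:100
    p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
    min(1, max(p, .Machine$double.xmin))
}

# Fraction of points of (x, y) in the four quadrants around (x0, y0);
# points on the dividing lines are split between quadrants like Press's
# quadct (strictly greater / less-or-equal).
.quadrantFractions <- function(x0, y0, x, y) {
    n <- length(x)
    gx <- x > x0; gy <- y > y0
    c(sum(gx & gy), sum(!gx & gy), sum(!gx & !gy), sum(gx & !gy)) / n
}

#' Two-sample two-dimensional Kolmogorov-Smirnov test
#'
#' The statistic is the largest difference, over the four quadrants around
#' every data point of either sample, between the two samples' point
#' fractions (averaged between using sample 1's and sample 2's points as
#' origins).  Significance uses the asymptotic one-dimensional KS tail
#' formula with the effective-n and correlation adjustment of the classical
#' two-dimensional recipe, which is accurate enough for screening;
#' p-values are clamped to (0, 1].
#'
#' @param x1,y1 coordinates of sample 1's points.
#' @param x2,y2 coordinates of sample 2's points.
#' @return a list with \code{D} and \code{p}.
#' @export
ks2d <- function(x1, y1, x2, y2) {
    n1 <- length(x1); n2 <- length(x2)
    stopifnot(n1 > 0L, n2 > 0L, length(y1) == n1, length(y2) == n2)
    maxdiff <- function(ox, oy) {
        d <- 0
        for (k in seq_along(ox)) {
            f1 <- .quadrantFractions(ox[k], oy[k], x1, y1)
            f2 <- .quadrantFractions(ox[k], oy[k], x2, y2)
            d <- max(d, max(abs(f1 - f2)))
        }
        d
    }
    D <- (maxdiff(x1, y1) + maxdiff(x2, y2)) / 2
    ne <- n1 * n2 / (n1 + n2)
    r2 <- function(x, y) {
        if (sd(x) == 0 || sd(y) == 0) 0 else cor(x, y)^2
    }
    rr <- sqrt(1 - (r2(x1, y1) + r2(x2, y2)) / 2)
    lambda <- sqrt(ne) * D / (1 + rr * (0.25 - 0.75 / sqrt(ne)))
    list(D = D, p = .qks(lambda))
}

#' Partition positions into gap-bounded runs
#'
#' Splits the retained positions into maximal runs on one chromosome with
#' adjacent positions at most \code{max_gap} bp apart.  The runs partition
#' the positions; segmentation never crosses a run boundary.
#'
#' @param gs a [GroupSummary-class] (sorted).
#' @param max_gap maximum within-run gap in bp (default 300).
#' @return a list of integer index vectors into \code{gs}.
#' @export
presegment <- function(gs, max_gap = 300L) {
    stopifnot(is(gs, "GroupSummary"))
    n <- length(gs)
    if (!n) return(list())
    chrom <- as.character(seqnames(gs)); pos <- start(gs)
    newrun <- c(TRUE, chrom[-1L] != chrom[-n] |
                      pos[-1L] - pos[-n] > max_gap)
    split(seq_len(n), cumsum(newrun))
}

# Proper sub-interval of `d` (length >= min_len) maximizing the circular-
# binary-segmentation contrast between the segment and the rest of the
# window, |mean(seg) - mean(rest)| / sqrt(1/n_seg + 1/n_rest).  The
# normalization keeps the criterion from collapsing onto the shortest
# high-mean core of a uniform block.  Ties broken leftmost first, then
# shortest.  Returns list(i, j, value), or NULL when no proper
# sub-interval of the required length exists.  The contrast is symmetric
# between an edge segment and its complement, so exact ties are broken by
# the larger deviation of the segment mean from the window mean (the side
# that actually changed), then leftmost, then shortest.
.maxMeanSegment <- function(d, min_len) {
    n <- length(d)
    if (n <= min_len) return(NULL)
    S <- c(0, cumsum(d))
    total <- S[n + 1L]
    winmean <- total / n
    best <- NULL
    eps <- 1e-12
    for (L in min_len:(n - 1L)) {
        segsum <- S[(L + 1L):(n + 1L)] - S[1:(n - L + 1L)]
        segmean <- segsum / L
        contrast <- abs(segmean - (total - segsum) / (n - L)) /
            sqrt(1 / L + 1 / (n - L))
        cmax <- max(contrast)
        cand <- which(contrast >= cmax - eps)
        dev <- abs(segmean[cand] - winmean)
        i <- cand[which.max(dev)]
        v <- contrast[i]; dv <- abs(segmean[i] - winmean)
        if (is.null(best) || v > best$value + eps ||
            (abs(v - best$value) <= eps &&
             (dv > best$dev + eps ||
              (abs(dv - best$dev) <= eps && i < best$i))))
            best <- list(i = i, j = i + L - 1L, value = v, dev = dv)
    }
    best
}

# 2D-KS p-value of a candidate (indices into gs): point sets
# (position rank, group mean rate) for the two groups.
.ks2dRegion <- function(m1, m2, idx) {
    rk <- seq_along(idx)
    ks2d(rk, m1[idx], rk, m2[idx])$p
}

#' Segment one run into candidate regions
#'
#' Recursive binary segmentation of the group-difference signal within one
#' gap-bounded run: at each level the sub-interval (of at least
#' \code{min_cpg} positions) maximizing the variance-normalized contrast
#' between its mean difference and that of the rest of the window is
#' selected; the split is accepted, and recursion descends
#' into the selected segment and its flanks, while the two-dimensional KS
#' p-value of the selected segment improves on (is smaller than) its
#' parent window's.  Windows that stop improving are emitted as terminal
#' candidates.
#'
#' @param gs a [GroupSummary-class].
#' @param run integer indices into \code{gs} (one run from [presegment()]).
#' @param params a [SegmentationParams()].
#' @return a list of integer index vectors (candidate regions).
#' @export
segmentRun <- function(gs, run, params = SegmentationParams()) {
    m <- groupMeans(gs)
    .segmentRunImpl(m[, 1L], m[, 2L], groupDiff(gs), run, params)
}

.segmentRunImpl <- function(m1, m2, d, run, params) {
    if (anyNA(d[run])) {
        warning("run skipped: undefined difference values")
        return(list())
    }
    min_cpg <- params$min_cpg
    recurse <- function(idx, p_parent) {
        n <- length(idx)
        if (n < min_cpg) return(list())
        best <- .maxMeanSegment(d[idx], min_cpg)
        if (is.null(best) || (best$i == 1L && best$j == n))
            return(list(idx))
        sub <- idx[best$i:best$j]
        p_best <- .ks2dRegion(m1, m2, sub)
        if (p_best < p_parent) {
            left <- if (best$i > 1L) idx[1:(best$i - 1L)] else integer()
            right <- if (best$j < n) idx[(best$j + 1L):n] else integer()
            c(recurse(sub, p_best),
              recurse(left, p_parent),
              recurse(right, p_parent))
        } else {
            list(idx)
        }
    }
    if (length(run) < min_cpg) return(list())
    recurse(run, .ks2dRegion(m1, m2, run))
}

# Segmentation of a noisy but truly uniform differential region can
# fracture it into adjacent pieces.  Before testing, candidates that are
# adjacent in position-index space, with mean differences of the same sign
# and both at least min_diff in magnitude, are merged back into one
# candidate.  Merging happens before any testing, so the BH correction
# sees the final candidate set.
.mergeAdjacentCandidates <- function(cands, dvec, min_diff) {
    if (length(cands) < 2L) return(cands)
    first <- vapply(cands, `[`, integer(1), 1L)
    o <- order(first)
    cands <- cands[o]
    out <- list(cands[[1L]])
    for (k in 2L:length(cands)) {
        prev <- out[[length(out)]]
        cur <- cands[[k]]
        mp <- mean(dvec[prev]); mc <- mean(dvec[cur])
        if (cur[1L] == prev[length(prev)] + 1L &&
            sign(mp) == sign(mc) &&
            abs(mp) >= min_diff && abs(mc) >= min_diff) {
            out[[length(out)]] <- c(prev, cur)
        } else {
            out[[length(out) + 1L]] <- cur
        }
    }
    out
}

#' Test a candidate region
#'
#' Computes the two nonparametric statistics for a candidate: a two-sided
#' Mann-Whitney U test comparing the per-position group-mean vectors, and
#' the two-dimensional KS test on the point sets (position rank, group mean
#' rate).  A degenerate candidate (zero variance in both groups and zero
#' difference) returns p = 1, flagged.
#'
#' @param gs a [GroupSummary-class].
#' @param idx integer indices of the candidate's positions.
#' @return a list with \code{p_mwu}, \code{p_ks2d} and \code{degenerate}.
#' @export
testRegion <- function(gs, idx) {
    m <- groupMeans(gs)
    .testRegionImpl(m[, 1L], m[, 2L], idx)
}

.testRegionImpl <- function(m1, m2, idx) {
    x <- m1[idx]; y <- m2[idx]
    if (sd(x) == 0 && sd(y) == 0 && all(x == y))
        return(list(p_mwu = 1, p_ks2d = 1, degenerate = TRUE))
    rk <- seq_along(idx)
    list(p_mwu = mannWhitneyU(x, y)$p,
         p_ks2d = ks2d(rk, x, rk, y)$p,
         degenerate = FALSE)
}

#' Call differentially methylated regions
#'
#' Runs the full DMR procedure: gap-bounded pre-segmentation, recursive
#' segmentation of the group-difference signal per run, nonparametric
#' testing of every candidate, genome-wide Benjamini-Hochberg correction of
#' the Mann-Whitney p-values (the designated primary test; the 2D-KS p is
#' reported alongside), and filtering by q-value, absolute mean difference,
#' CpG count and optional length.  Output is sorted and deterministically
#' named \code{DMR_<k>}.
#'
#' @param gs a [GroupSummary-class].
#' @param params a [SegmentationParams()].
#' @return a [DMRSet-class]; its metadata (via \code{S4Vectors::metadata})
#'   records every tested candidate in \code{candidates} for diagnostics.
#' @export
callDMRs <- function(gs, params = SegmentationParams()) {
    stopifnot(is(gs, "GroupSummary"), inherits(params, "SegmentationParams"))
    runs <- presegment(gs, params$max_gap)
    m <- groupMeans(gs)
    m1 <- m[, 1L]; m2 <- m[, 2L]; dvec <- groupDiff(gs)
    cands <- list()
    for (run in runs)
        cands <- c(cands, .segmentRunImpl(m1, m2, dvec, run, params))
    cands <- .mergeAdjacentCandidates(cands, dvec, params$min_diff)
    empty <- new("DMRSet",
                 GRanges(name = character(), n_cpg = integer(),
                         mean_g1 = numeric(), mean_g2 = numeric(),
                         mean_diff = numeric(), p_mwu = numeric(),
                         p_ks2d = numeric(), q = numeric(),
                         direction = character()),
                 params = unclass(params))
    if (!length(cands)) return(empty)
    if (length(cands) < 2L)
        message("fewer than 2 candidates; BH correction is degenerate (q = p)")
    tests <- lapply(cands, function(idx) .testRegionImpl(m1, m2, idx))
    p_mwu <- vapply(tests, `[[`, numeric(1), "p_mwu")
    p_ks <- vapply(tests, `[[`, numeric(1), "p_ks2d")
    q <- p.adjust(p_mwu, method = "BH")
    chrom <- as.character(seqnames(gs)); pos <- start(gs)
    stats <- data.frame(
        chrom = vapply(cands, function(i) chrom[i[1L]], character(1)),
        start = vapply(cands, function(i) min(pos[i]), numeric(1)),
        end = vapply(cands, function(i) max(pos[i]), numeric(1)),
        n_cpg = lengths(cands),
        mean_g1 = vapply(cands, function(i) mean(m[i, 1L]), numeric(1)),
        mean_g2 = vapply(cands, function(i) mean(m[i, 2L]), numeric(1)),
        p_mwu = p_mwu, p_ks2d = p_ks, q = q)
    stats$mean_diff <- stats$mean_g1 - stats$mean_g2
    keep <- stats$q <= params$max_q &
        abs(stats$mean_diff) >= params$min_diff &
        stats$n_cpg >= params$min_cpg
    if (!is.null(params$min_length_nt))
        keep <- keep & (stats$end - stats$start + 1L) >= params$min_length_nt
    kept <- stats[keep, , drop = FALSE]
    if (!nrow(kept)) {
        metadata(empty)$candidates <- stats
        return(empty)
    }
    o <- order(kept$chrom, kept$start, kept$end)
    kept <- kept[o, , drop = FALSE]
    gr <- GRanges(kept$chrom, IRanges(kept$start, kept$end),
                  name = paste0("DMR_", seq_len(nrow(kept))),
                  n_cpg = as.integer(kept$n_cpg),
                  mean_g1 = kept$mean_g1, mean_g2 = kept$mean_g2,
                  mean_diff = kept$mean_diff,
                  p_mwu = kept$p_mwu, p_ks2d = kept$p_ks2d, q = kept$q,
                  direction = ifelse(kept$mean_diff > 0, "hyper", "hypo"))
    out <- new("DMRSet", gr, params = unclass(params))
    metadata(out)$candidates <- stats
    out
}

#' Summary tables for a DMR set
#'
#' The standard post-calling overview: histograms of DMR length (nt and CpG
#' count) and absolute mean difference, the (mean_g1, mean_g2) correlation
#' scatter, and the (mean_diff, q) scatter.
#'
#' @param dmrs a [DMRSet-class].
#' @return a list of data.frames: \code{length_nt}, \code{length_cpg},
#'   \code{abs_diff} (histogram counts summing to the DMR count), and
#'   \code{scatter_means}, \code{scatter_diff_q}.
#' @export
dmrStatistics <- function(dmrs) {
    stopifnot(is(dmrs, "DMRSet"))
    mc <- mcols(dmrs)
    histdf <- function(x, breaks) {
        h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                            include.lowest = TRUE, right = FALSE)
        data.frame(bin_lo = h$breaks[-length(h$breaks)],
                   bin_hi = h$breaks[-1L], n = h$counts)
    }
    if (!length(dmrs)) {
        e <- data.frame(bin_lo = numeric(), bin_hi = numeric(), n = integer())
        return(list(length_nt = e, length_cpg = e, abs_diff = e,
                    scatter_means = data.frame(mean_g1 = numeric(),
                                               mean_g2 = numeric()),
                    scatter_diff_q = data.frame(mean_diff = numeric(),
                                                q = numeric())))
    }
    w <- width(dmrs)
    list(length_nt = histdf(w, pretty(c(0, max(w)), n = 20)),
         length_cpg = histdf(mc$n_cpg, pretty(c(0, max(mc$n_cpg)), n = 20)),
         abs_diff = histdf(abs(mc$mean_diff), seq(0, 1, by = 0.05)),
         scatter_means = data.frame(mean_g1 = mc$mean_g1,
                                    mean_g2 = mc$mean_g2),
         scatter_diff_q = data.frame(mean_diff = mc$mean_diff, q = mc$q))
}
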