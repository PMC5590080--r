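# Aggregating methylation over annotation regions (TFBS, CpG islands,
# shores, promoters, ...) and clustering the resulting region heatmap.

#' Mean methylation per region and sample
#'
#' For every annotation region and sample, averages the sample's non-missing
#' rates over the positions falling inside the region (BED-style 0-based
#' half-open overlap).  Cells backed by fewer than \code{min_positions}
#' positions are set missing; a single-CpG "region mean" is noise-dominated.
#' Overlapping regions are scored independently, so one position may
#' contribute to several regions.  Regions with all cells missing are
#' dropped from the table but counted in the report.
#'
#' @param mm a nonempty [MethylationMatrix-class].
#' @param regions a GRanges with unique \code{name}s (see [readBed()]).
#' @param min_positions minimum contributing positions per cell (default 3).
#' @param group1,group2 optional sample-name vectors; when given, per-region
#'   group means (mean over the group's non-missing cells) are appended.
#' @return a list with \code{table} (regions x samples matrix of means),
#'   \code{n_positions} (same shape, contributing-position counts),
#'   \code{group_means} (data.frame, or NULL) and \code{report} (counts of
#'   regions in/kept/dropped).
#' @export
aggregateOverRegions <- function(mm, regions, min_positions = 3L,
                                 group1 = NULL, group2 = NULL) {
    stopifnot(is(mm, "MethylationMatrix"))
    if (!length(regions)) stop("empty region set")
    if (!nrow(mm)) stop("empty methylation matrix")
    nm <- mcols(regions)$name
    if (is.null(nm)) nm <- paste0("region_", seq_along(regions))
    if (anyDuplicated(nm)) stop("region names must be unique")
    hits <- GenomicRanges::findOverlaps(rowRanges(mm), regions,
                                        ignore.strand = TRUE)
    r <- methRate(mm)
    nr <- length(regions); ns <- ncol(mm)
    tab <- matrix(NA_real_, nr, ns, dimnames = list(nm, colnames(mm)))
    npos <- matrix(0L, nr, ns, dimnames = list(nm, colnames(mm)))
    if (length(hits)) {
        qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
        for (s in seq_len(ns)) {
            v <- r[qh, s]
            ok <- !is.na(v)
            cnt <- tapply(ok, sh, sum)
            sums <- tapply(ifelse(ok, v, 0), sh, sum)
            ridx <- as.integer(names(cnt))
            npos[ridx, s] <- as.integer(cnt)
            good <- cnt >= min_positions
            tab[ridx[good], s] <- sums[good] / cnt[good]
        }
    }
    all_missing <- rowSums(!is.na(tab)) == 0L
    gm <- NULL
    if (!is.null(group1) && !is.null(group2)) {
        gm <- data.frame(
            name = nm,
            mean_g1 = rowMeans(tab[, group1, drop = FALSE], na.rm = TRUE),
            mean_g2 = rowMeans(tab[, group2, drop = FALSE], na.rm = TRUE))
        gm <- gm[!all_missing, , drop = FALSE]
    }
    list(table = tab[!all_missing, , drop = FALSE],
         n_positions = npos,
         group_means = gm,
         report = data.frame(n_regions = nr,
                             n_kept = sum(!all_missing),
                             n_dropped = sum(all_missing)))
}

#' Cluster a region-by-sample methylation table
#'
#' Hierarchically clusters both rows (regions) and columns (samples) of the
#' aggregated table with the same metric and linkage used for the sample
#' overview: Euclidean distance over pairwise-shared non-missing entries,
#' complete linkage.  Output is deterministic given the input.
#'
#' @param table a numeric matrix as returned by [aggregateOverRegions()],
#'   with >= 2 rows and >= 2 columns.
#' @return a list with \code{row_order}, \code{col_order} (permutations),
#'   and \code{row_hclust}, \code{col_hclust} trees.
#' @export
clusterRegionHeatmap <- function(table) {
    if (is.null(dim(table)) || nrow(table) < 2L || ncol(table) < 2L)
        stop("need >= 2 regions and >= 2 samples after dropping all-missing ",
             "regions; consider relaxing min_positions")
    dr <- .pairwiseSharedDist(t(table))
    dc <- .pairwiseSharedDist(table)
    if (anyNA(dr) || anyNA(dc))
        stop("undefined distances (too few shared entries); consider ",
             "relaxing min_positions")
    rh <- hclust(stats::as.dist(dr), method = "complete")
    ch <- hclust(stats::as.dist(dc), method = "complete")
    list(row_order = rh$order, col_order = ch$order,
         row_hclust = rh, col_hclust = ch)
}

#' Per-region and per-sample mean boxplot data
#'
#' Two complementary poolings of an aggregated table: the distribution of
#' per-region means pooled over samples, and of per-sample means pooled
#' over regions.
#'
#' @param table a regions-by-samples matrix from [aggregateOverRegions()].
#' @return a list with \code{per_region} (named vector: mean over samples
#'   per region) and \code{per_sample} (mean over regions per sample).
#' @export
regionBoxplotData <- function(table) {
    list(per_region = rowMeans(table, na.rm = TRUE),
         per_sample = colMeans(table, na.rm = TRUE))
}
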