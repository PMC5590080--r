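# DMR-expression integration: correlate per-sample DMR methylation with the
# expression of associated genes to nominate correlating DMRs (cDMRs).

#' Correlate DMR methylation with gene expression
#'
#' For each supplied DMR-gene pair, computes the per-sample mean methylation
#' over the DMR's positions (missing when fewer than 2 of the sample's
#' positions are covered), pairs it with the gene's expression, and reports
#' the Pearson (linear) and Spearman (rank, monotone-invariant) correlation
#' coefficients over the samples with both values present.  Pairs with
#' fewer than 3 usable samples are flagged and their coefficients withheld;
#' a zero-variance vector makes a coefficient undefined (flagged, not
#' NaN-propagated).
#'
#' @param dmrs a [DMRSet-class].
#' @param mm a [MethylationMatrix-class].
#' @param expression numeric matrix, genes x samples (see
#'   [readExpressionTable()]); at least 3 sample names must be shared with
#'   \code{mm}.
#' @param pairs data.frame with columns \code{dmr_id}, \code{gene_id}.
#' @return a list of per-pair records, each with \code{dmr_id},
#'   \code{gene_id}, \code{pearson_r}, \code{spearman_rho},
#'   \code{n_samples}, \code{flag} (\code{"ok"}, \code{"too_few_samples"}
#'   or \code{"zero_variance"}) and \code{points} (per-sample methylation /
#'   expression data.frame).
#' @export
correlatePairs <- function(dmrs, mm, expression, pairs) {
    stopifnot(is(dmrs, "DMRSet"), is(mm, "MethylationMatrix"))
    shared <- intersect(colnames(mm), colnames(expression))
    if (length(shared) < 3L)
        stop("fewer than 3 samples shared between methylation and expression")
    bad_dmr <- setdiff(pairs$dmr_id, mcols(dmrs)$name)
    bad_gene <- setdiff(pairs$gene_id, rownames(expression))
    if (length(bad_dmr) || length(bad_gene))
        stop("unknown identifiers -- DMRs: ",
             paste(bad_dmr, collapse = ", "), "; genes: ",
             paste(bad_gene, collapse = ", "))
    r <- methRate(mm)[, shared, drop = FALSE]
    hits <- GenomicRanges::findOverlaps(rowRanges(mm), dmrs,
                                        ignore.strand = TRUE)
    rows_of <- split(S4Vectors::queryHits(hits),
                     mcols(dmrs)$name[S4Vectors::subjectHits(hits)])
    lapply(seq_len(nrow(pairs)), function(k) {
        did <- pairs$dmr_id[k]; gid <- pairs$gene_id[k]
        rows <- rows_of[[did]]
        meth <- if (is.null(rows)) rep(NA_real_, length(shared)) else {
            sub <- r[rows, , drop = FALSE]
            n_cov <- colSums(!is.na(sub))
            ifelse(n_cov >= 2L, colMeans(sub, na.rm = TRUE), NA_real_)
        }
        expr <- expression[gid, shared]
        use <- !is.na(meth) & !is.na(expr)
        pts <- data.frame(sample = shared, methylation = as.numeric(meth),
                          expression = as.numeric(expr))
        rec <- list(dmr_id = did, gene_id = gid, pearson_r = NA_real_,
                    spearman_rho = NA_real_, n_samples = sum(use),
                    flag = "ok", points = pts)
        if (sum(use) < 3L) {
            rec$flag <- "too_few_samples"
        } else if (sd(meth[use]) == 0 || sd(expr[use]) == 0) {
            rec$flag <- "zero_variance"
        } else {
            rec$pearson_r <- cor(meth[use], expr[use], method = "pearson")
            rec$spearman_rho <- cor(meth[use], expr[use], method = "spearman")
        }
        rec
    })
}

#' Rank correlating DMRs
#'
#' A pair is a cDMR when the larger of its two absolute coefficients reaches
#' the cutoff; anticorrelation counts (promoter methylation typically
#' represses expression, so strong negative correlations are the
#' interesting ones).
#'
#' @param records output of [correlatePairs()].
#' @param cutoff absolute-coefficient threshold (default 0.8).
#' @return a list with \code{table}: a data.frame of all scored pairs sorted
#'   by descending best absolute coefficient, with an \code{is_cdmr}
#'   column; and \code{cdmrs}: the rows passing the cutoff.
#' @export
correlationReport <- function(records, cutoff = 0.8) {
    stopifnot(cutoff >= 0)
    tab <- do.call(rbind, lapply(records, function(rec)
        data.frame(dmr_id = rec$dmr_id, gene_id = rec$gene_id,
                   pearson_r = rec$pearson_r,
                   spearman_rho = rec$spearman_rho,
                   n_samples = rec$n_samples, flag = rec$flag)))
    if (is.null(tab))
        tab <- data.frame(dmr_id = character(), gene_id = character(),
                          pearson_r = numeric(), spearman_rho = numeric(),
                          n_samples = integer(), flag = character())
    best <- pmax(abs(tab$pearson_r), abs(tab$spearman_rho), na.rm = FALSE)
    best[is.na(best)] <- -Inf
    tab$best_abs_coef <- ifelse(is.finite(best), best, NA_real_)
    tab$is_cdmr <- is.finite(best) & best >= cutoff & tab$flag == "ok"
    tab <- tab[order(-best), , drop = FALSE]
    rownames(tab) <- NULL
    list(table = tab, cdmrs = tab[tab$is_cdmr, , drop = FALSE])
}
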