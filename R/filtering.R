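# Coverage- and context-based filtering of called cytosines.

#' Specify a coverage/context filter
#'
#' Lowly covered positions carry unreliable rate estimates; very highly
#' covered ones are typically mapping artifacts (repeats, PCR stacks).  The
#' upper cutoff may be an absolute cap or, by default, a quantile of the
#' sample's own coverage distribution so that it adapts to library depth.
#'
#' @param min_coverage minimum coverage, inclusive (default 10).
#' @param max_coverage absolute upper cap, inclusive (\code{Inf} = none).
#'   When \code{NULL} (default) the cap is resolved from
#'   \code{max_coverage_quantile}.
#' @param max_coverage_quantile quantile of the input coverage distribution
#'   above which positions are removed (default 0.999; ignored when an
#'   absolute \code{max_coverage} is given).
#' @param contexts contexts to keep (default \code{"CG"}, the dominant
#'   methylated context in mammals).
#' @return a list of class \code{FilterSpec}.
#' @export
FilterSpec <- function(min_coverage = 10L, max_coverage = NULL,
                       max_coverage_quantile = 0.999, contexts = "CG") {
    stopifnot(min_coverage >= 0, all(contexts %in% .CONTEXTS))
    if (!is.null(max_coverage) && is.finite(max_coverage) &&
        max_coverage < min_coverage)
        stop("max_coverage must be >= min_coverage")
    structure(list(min_coverage = min_coverage, max_coverage = max_coverage,
                   max_coverage_quantile = max_coverage_quantile,
                   contexts = unique(contexts)),
              class = "FilterSpec")
}

#' Filter methylation calls by coverage and context
#'
#' A record survives iff \code{min_coverage <= coverage <= resolved max} and
#' its context is among \code{spec$contexts}.  Both bounds are inclusive.
#' Filtering is idempotent for an absolute upper cap; with a quantile rule
#' the cap is resolved once from the input's coverage distribution and
#' reported, so the same resolved spec can be re-applied.
#'
#' @param calls a [MethylationCalls-class] object.
#' @param spec a [FilterSpec()].
#' @return a list with \code{calls} (the survivors) and \code{report}: a
#'   data.frame of input/output counts per context plus the resolved
#'   maximum-coverage cutoff (attribute \code{max_coverage}).
#' @export
filterCalls <- function(calls, spec = FilterSpec()) {
    stopifnot(is(calls, "MethylationCalls"), inherits(spec, "FilterSpec"))
    cov <- methCoverage(calls)
    maxc <- if (!is.null(spec$max_coverage)) spec$max_coverage
            else if (length(cov))
                as.numeric(quantile(cov, spec$max_coverage_quantile,
                                    type = 1L))
            else Inf
    ctx <- methContext(calls)
    keep <- cov >= spec$min_coverage & cov <= maxc & ctx %in% spec$contexts
    kept <- calls[keep]
    report <- data.frame(
        context = .CONTEXTS,
        n_in = as.integer(table(factor(ctx, levels = .CONTEXTS))),
        n_out = as.integer(table(factor(ctx[keep], levels = .CONTEXTS))))
    attr(report, "max_coverage") <- maxc
    attr(report, "min_coverage") <- spec$min_coverage
    list(calls = kept, report = report)
}

#' Coverage and methylation-rate distributions before/after filtering
#'
#' Returns the histogram data behind the usual filtering diagnostics: the
#' coverage distribution and the methylation-rate distribution (100 bins
#' over [0,1]) of the complete and the filtered position sets.  Rate bins
#' are left-closed right-open except the last, \code{[0.99, 1]}, which is
#' closed so a fully methylated position lands in the final bin.
#'
#' @param before,after [MethylationCalls-class] objects.
#' @return a list with \code{coverage} (data.frame: coverage, n_before,
#'   n_after) and \code{rate} (data.frame: bin_lo, bin_hi, n_before,
#'   n_after).
#' @export
distributionSummaries <- function(before, after) {
    covb <- methCoverage(before); cova <- methCoverage(after)
    covs <- sort(unique(c(covb, cova)))
    coverage <- data.frame(
        coverage = covs,
        n_before = as.integer(table(factor(covb, levels = covs))),
        n_after = as.integer(table(factor(cova, levels = covs))))
    brk <- (0:100) / 100  # division form: boundary rates bin exactly
    binof <- function(r) pmin(findInterval(r, brk, rightmost.closed = TRUE),
                              100L)
    rate <- data.frame(
        bin_lo = brk[-101L], bin_hi = brk[-1L],
        n_before = as.integer(table(factor(binof(methRate(before)),
                                           levels = 1:100))),
        n_after = as.integer(table(factor(binof(methRate(after)),
                                          levels = 1:100))))
    list(coverage = coverage, rate = rate)
}

#' Merge the two strands of symmetric CpG dinucleotides
#'
#' A CpG on the forward strand (position p) and its reverse-strand partner
#' (the G at p+1) measure the same palindromic site; destranding sums their
#' counts into a single forward-strand record at p.  Non-CG records and
#' unpaired CpG strands pass through unchanged.
#'
#' @param calls a [MethylationCalls-class] object.
#' @return a [MethylationCalls-class] object with symmetric CpG pairs merged.
#' @export
destrandCpG <- function(calls) {
    stopifnot(is(calls, "MethylationCalls"))
    if (!length(calls)) return(calls)
    ctx <- methContext(calls)
    std <- as.character(strand(calls))
    cg_plus <- which(ctx == "CG" & std == "+")
    cg_minus <- which(ctx == "CG" & std == "-")
    key_plus <- paste0(seqnames(calls)[cg_plus], ":", start(calls)[cg_plus])
    key_minus <- paste0(seqnames(calls)[cg_minus], ":",
                        start(calls)[cg_minus] - 1L)
    hit <- match(key_minus, key_plus)
    paired_minus <- cg_minus[!is.na(hit)]
    partner_plus <- cg_plus[hit[!is.na(hit)]]
    nm <- nMeth(calls); nu <- nUnmeth(calls)
    nm[partner_plus] <- nm[partner_plus] + nm[paired_minus]
    nu[partner_plus] <- nu[partner_plus] + nu[paired_minus]
    keep <- setdiff(seq_along(calls), paired_minus)
    MethylationCalls(as.character(seqnames(calls))[keep],
                     start(calls)[keep],
                     as.character(strand(calls))[keep],
                     ctx[keep], nm[keep], nu[keep])
}
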