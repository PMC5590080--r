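# Minimal base-graphics renderers for the standard diagnostic figures.

#' Plot coverage and rate distributions before/after filtering
#'
#' @param summaries output of [distributionSummaries()].
#' @export
plotDistributions <- function(summaries) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    cv <- summaries$coverage
    graphics::plot(cv$coverage, cv$n_before, type = "h", col = "grey60",
                   xlab = "coverage", ylab = "positions",
                   main = "Coverage distribution")
    graphics::points(cv$coverage, cv$n_after, type = "h", col = "firebrick")
    graphics::legend("topright", c("all", "filtered"), lwd = 2,
                     col = c("grey60", "firebrick"), bty = "n")
    rt <- summaries$rate
    graphics::plot(rt$bin_lo, rt$n_before, type = "s", col = "grey60",
                   xlab = "methylation rate", ylab = "positions",
                   main = "Methylation rate distribution")
    graphics::lines(rt$bin_lo, rt$n_after, type = "s", col = "firebrick")
    invisible(NULL)
}

#' Plot the DMR overview panels
#'
#' @param stats output of [dmrStatistics()].
#' @export
plotDmrStatistics <- function(stats) {
    op <- graphics::par(mfrow = c(2, 2))
    on.exit(graphics::par(op))
    graphics::barplot(stats$length_nt$n,
                      names.arg = stats$length_nt$bin_lo,
                      main = "DMR length (nt)", las = 2, cex.names = 0.6)
    graphics::barplot(stats$abs_diff$n, names.arg = stats$abs_diff$bin_lo,
                      main = "|mean difference|", las = 2, cex.names = 0.6)
    graphics::plot(stats$scatter_means, xlim = 0:1, ylim = 0:1,
                   main = "Group means", xlab = "group 1", ylab = "group 2")
    graphics::abline(0, 1, col = "grey")
    graphics::plot(stats$scatter_diff_q$mean_diff,
                   -log10(pmax(stats$scatter_diff_q$q, 1e-300)),
                   xlab = "mean difference", ylab = "-log10 q",
                   main = "Difference vs significance")
    invisible(NULL)
}
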