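#' @import methods
#' @import GenomicRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame Rle
#' @importFrom IRanges IRanges ranges
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths sortSeqlevels
#' @importFrom BiocGenerics start end width strand strand<-
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData
#'   assay assays assayNames
#' @importFrom stats p.adjust rbeta rbinom rpois rnorm runif setNames median
#'   quantile fivenum hclust dist as.dendrogram cor sd complete.cases pnorm
#' @importFrom utils read.table write.table head tail combn
NULL

.CONTEXTS <- c("CG", "CHG", "CHH")

#' Per-cytosine methylation calls
#'
#' A \linkS4class{GRanges}-derived container holding one record per reference
#' cytosine of a single sample.  Each range has width 1 (the position of the C
#' on the forward strand; minus-strand records refer to a G on the forward
#' reference sequence), strand \code{+} or \code{-}, and metadata columns
#' \code{context} (\code{CG}, \code{CHG} or \code{CHH}), \code{n_meth}
#' (reads supporting methylation, i.e. an unconverted C), \code{n_unmeth}
#' (reads supporting non-methylation, a converted C read as T) and
#' \code{rate} = \code{n_meth / (n_meth + n_unmeth)}.
#'
#' Records with zero coverage are not representable: the rate would be
#' undefined, so such positions are simply absent.
#'
#' @seealso [MethylationCalls()] for construction,
#'   [readMethylationVcf()] / [writeMethylationVcf()] for on-disk form.
#' @export
setClass("MethylationCalls", contains = "GRanges")

setValidity("MethylationCalls", function(object) {
    msg <- character()
    mc <- mcols(object)
    need <- c("context", "n_meth", "n_unmeth", "rate")
    miss <- setdiff(need, colnames(mc))
    if (length(miss))
        return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
    if (length(object)) {
        if (any(width(object) != 1L))
            msg <- c(msg, "all ranges must have width 1")
        if (!all(as.character(strand(object)) %in% c("+", "-")))
            msg <- c(msg, "strand must be '+' or '-'")
        if (!all(mc$context %in% .CONTEXTS))
            msg <- c(msg, "context must be one of CG, CHG, CHH")
        if (any(mc$n_meth < 0L) || any(mc$n_unmeth < 0L))
            msg <- c(msg, "counts must be non-negative")
        cov <- mc$n_meth + mc$n_unmeth
        if (any(cov == 0L))
            msg <- c(msg, "zero-coverage records are not allowed (rate undefined)")
        bad <- abs(mc$rate - mc$n_meth / pmax(cov, 1L)) > 1e-9
        if (any(bad & cov > 0L))
            msg <- c(msg, "rate inconsistent with n_meth / (n_meth + n_unmeth)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a MethylationCalls object
#'
#' @param chrom character vector of chromosome names.
#' @param pos 1-based positions of the cytosines on the forward strand.
#' @param strand \code{"+"} or \code{"-"} per position.
#' @param context \code{"CG"}, \code{"CHG"} or \code{"CHH"} per position.
#' @param n_meth,n_unmeth non-negative integer read counts supporting the
#'   methylated / unmethylated state.  Their sum (the coverage) must be
#'   positive for every record.
#' @param sort sort records by (chrom, pos)?  Default \code{TRUE}.
#' @return A [MethylationCalls-class] object with the \code{rate} column
#'   computed from the counts.
#' @examples
#' mc <- MethylationCalls("chr1", c(101L, 150L), c("+", "-"),
#'                        c("CG", "CG"), n_meth = c(3L, 0L),
#'                        n_unmeth = c(1L, 5L))
#' methRate(mc)
#' @export
MethylationCalls <- function(chrom = character(), pos = integer(),
                             strand = character(), context = character(),
                             n_meth = integer(), n_unmeth = integer(),
                             sort = TRUE) {
    n_meth <- as.integer(n_meth)
    n_unmeth <- as.integer(n_unmeth)
    if (any(pos < 1L))
        stop("positions must be >= 1 (1-based forward-strand coordinates)")
    cov <- n_meth + n_unmeth
    gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L), strand = strand,
                  context = as.character(context),
                  n_meth = n_meth, n_unmeth = n_unmeth,
                  rate = ifelse(cov > 0L, n_meth / cov, NA_real_))
    if (sort) gr <- GenomicRanges::sort(sortSeqlevels(gr), ignore.strand = TRUE)
    new("MethylationCalls", gr)
}

#' Positions-by-samples methylation matrix
#'
#' A \linkS4class{RangedSummarizedExperiment} with one row per cytosine
#' position (the union over samples) and one column per sample.  Two assays:
#' \code{rate} (methylation level in [0,1], \code{NA} where a sample lacks
#' sufficient coverage -- missingness is explicit, a rate of 0 is meaningful)
#' and \code{coverage} (reads observed, 0 where absent).  Row ranges carry
#' \code{context} and are sorted by (chrom, pos).
#'
#' @seealso [buildSampleMatrix()]
#' @export
setClass("MethylationMatrix", contains = "RangedSummarizedExperiment")

setValidity("MethylationMatrix", function(object) {
    msg <- character()
    if (!all(c("rate", "coverage") %in% assayNames(object)))
        return("assays 'rate' and 'coverage' are required")
    r <- assay(object, "rate")
    if (any(r < 0 | r > 1, na.rm = TRUE))
        msg <- c(msg, "rates must lie in [0, 1] or be NA")
    if (is.null(colnames(object)) && ncol(object) > 0)
        msg <- c(msg, "sample (column) names are required")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample names")
    if (!"context" %in% colnames(mcols(rowRanges(object))))
        msg <- c(msg, "rowRanges must carry a 'context' column")
    if (length(msg)) msg else TRUE
})

#' Two-group per-position methylation summary
#'
#' A \linkS4class{GRanges}-derived object with one row per position retained
#' by the minimum-samples rule, carrying \code{mean_g1}, \code{mean_g2}
#' (arithmetic group means of the non-missing sample rates), \code{diff}
#' = \code{mean_g1 - mean_g2}, and \code{n_covered_g1}/\code{n_covered_g2}
#' (samples with sufficient coverage).  Slots record the group memberships.
#'
#' @slot group1,group2 character vectors of sample names.
#' @slot minSamples the per-group minimum-samples threshold applied.
#' @seealso [summarizeGroups()]
#' @export
setClass("GroupSummary", contains = "GRanges",
         representation(group1 = "character", group2 = "character",
                        minSamples = "integer"))

setValidity("GroupSummary", function(object) {
    mc <- mcols(object)
    need <- c("mean_g1", "mean_g2", "diff", "n_covered_g1", "n_covered_g2")
    miss <- setdiff(need, colnames(mc))
    if (length(miss))
        return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
    if (length(object)) {
        ok <- is.na(mc$diff) | abs(mc$diff - (mc$mean_g1 - mc$mean_g2)) < 1e-9
        if (!all(ok)) return("diff must equal mean_g1 - mean_g2")
    }
    if (length(intersect(object@group1, object@group2)))
        return("groups must be disjoint")
    TRUE
})

#' A set of differentially methylated regions
#'
#' \linkS4class{GRanges}-derived; each range is one DMR (0-based half-open on
#' disk, 1-based closed as a GRanges) with metadata columns \code{name}
#' (\code{DMR_<k>} in sort order), \code{n_cpg}, \code{mean_g1},
#' \code{mean_g2}, \code{mean_diff}, \code{p_mwu} (Mann-Whitney U p),
#' \code{p_ks2d} (two-dimensional Kolmogorov-Smirnov p), \code{q}
#' (Benjamini-Hochberg over \code{p_mwu} across all tested candidates) and
#' \code{direction} (\code{hyper} iff \code{mean_diff > 0}, w.r.t. group 1).
#'
#' @slot params the [SegmentationParams()] list the set was called with.
#' @seealso [callDMRs()]
#' @export
setClass("DMRSet", contains = "GRanges",
         representation(params = "list"))

setValidity("DMRSet", function(object) {
    mc <- mcols(object)
    need <- c("name", "n_cpg", "mean_g1", "mean_g2", "mean_diff",
              "p_mwu", "p_ks2d", "q", "direction")
    miss <- setdiff(need, colnames(mc))
    if (length(miss))
        return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
    if (length(object)) {
        if (any(mc$n_cpg < 2L)) return("every DMR must span >= 2 tested positions")
        if (any(abs(mc$mean_diff - (mc$mean_g1 - mc$mean_g2)) > 1e-9))
            return("mean_diff must equal mean_g1 - mean_g2")
        dir_ok <- ifelse(mc$mean_diff > 0, mc$direction == "hyper",
                         mc$direction == "hypo")
        if (!all(dir_ok)) return("direction inconsistent with sign of mean_diff")
    }
    TRUE
})
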