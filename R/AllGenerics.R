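#' @rdname MethylationCalls-accessors
#' @export
setGeneric("nMeth", function(x) standardGeneric("nMeth"))
#' @rdname MethylationCalls-accessors
#' @export
setGeneric("nUnmeth", function(x) standardGeneric("nUnmeth"))
#' @rdname MethylationCalls-accessors
#' @export
setGeneric("methRate", function(x) standardGeneric("methRate"))
#' @rdname MethylationCalls-accessors
#' @export
setGeneric("methCoverage", function(x) standardGeneric("methCoverage"))
#' @rdname MethylationCalls-accessors
#' @export
setGeneric("methContext", function(x) standardGeneric("methContext"))

#' Accessors for methylation containers
#'
#' \code{nMeth}, \code{nUnmeth}: methylated / unmethylated read counts.
#' \code{methCoverage}: their sum.  \code{methRate}: methylation level
#' (\code{n_meth / coverage}).  \code{methContext}: trinucleotide context.
#'
#' @param x a [MethylationCalls-class] object (or, for \code{methRate} and
#'   \code{methCoverage}, a [MethylationMatrix-class], returning the assay).
#' @return numeric, integer or character vectors parallel to \code{x}; for
#'   matrices, a positions-by-samples matrix.
#' @name MethylationCalls-accessors
NULL

#' @rdname MethylationCalls-accessors
setMethod("nMeth", "MethylationCalls", function(x) mcols(x)$n_meth)
#' @rdname MethylationCalls-accessors
setMethod("nUnmeth", "MethylationCalls", function(x) mcols(x)$n_unmeth)
#' @rdname MethylationCalls-accessors
setMethod("methRate", "MethylationCalls", function(x) mcols(x)$rate)
#' @rdname MethylationCalls-accessors
setMethod("methCoverage", "MethylationCalls",
          function(x) mcols(x)$n_meth + mcols(x)$n_unmeth)
#' @rdname MethylationCalls-accessors
setMethod("methContext", "MethylationCalls", function(x) mcols(x)$context)

#' @rdname MethylationCalls-accessors
setMethod("methRate", "MethylationMatrix", function(x) assay(x, "rate"))
#' @rdname MethylationCalls-accessors
setMethod("methCoverage", "MethylationMatrix", function(x) assay(x, "coverage"))
#' @rdname MethylationCalls-accessors
setMethod("methContext", "MethylationMatrix",
          function(x) mcols(rowRanges(x))$context)

#' @rdname GroupSummary-accessors
#' @export
setGeneric("groupMeans", function(x) standardGeneric("groupMeans"))
#' @rdname GroupSummary-accessors
#' @export
setGeneric("groupDiff", function(x) standardGeneric("groupDiff"))

#' Accessors for GroupSummary
#'
#' \code{groupMeans}: two-column matrix of per-position group mean rates.
#' \code{groupDiff}: \code{mean_g1 - mean_g2} per position.
#'
#' @param x a [GroupSummary-class] object.
#' @name GroupSummary-accessors
NULL

#' @rdname GroupSummary-accessors
setMethod("groupMeans", "GroupSummary", function(x)
    cbind(g1 = mcols(x)$mean_g1, g2 = mcols(x)$mean_g2))
#' @rdname GroupSummary-accessors
setMethod("groupDiff", "GroupSummary", function(x) mcols(x)$diff)

setMethod("show", "MethylationCalls", function(object) {
    cat(class(object), "with", length(object), "cytosine record(s)\n")
    if (length(object)) {
        tab <- table(factor(mcols(object)$context, levels = .CONTEXTS))
        cat("  contexts:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
        cat("  median coverage:", median(methCoverage(object)),
            " mean rate:", round(mean(methRate(object)), 4), "\n")
    }
    invisible(callNextMethod())
})

setMethod("show", "GroupSummary", function(object) {
    cat(class(object), "with", length(object), "position(s)\n")
    cat("  group1:", paste(object@group1, collapse = ", "), "\n")
    cat("  group2:", paste(object@group2, collapse = ", "), "\n")
    cat("  min samples per group:", object@minSamples, "\n")
    invisible(callNextMethod())
})

setMethod("show", "DMRSet", function(object) {
    cat(class(object), "with", length(object), "DMR(s)\n")
    if (length(object)) {
        mc <- mcols(object)
        cat("  hyper:", sum(mc$direction == "hyper"),
            " hypo:", sum(mc$direction == "hypo"), "\n")
        cat("  median width:", median(width(object)), "nt;",
            "median CpGs:", median(mc$n_cpg), "\n")
    }
    invisible(callNextMethod())
})
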