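# Declarative end-to-end runner: one config, all stages in dependency
# order (call -> filter -> summarize -> annotate / dmr -> correlate), with
# fail-fast validation before any computation and a machine-readable run
# manifest.  The companion shell entry point (inst/scripts/meth.R) exposes
# each stage as a subcommand over the same functions.

.cfgGet <- function(cfg, path, default = NULL) {
    for (k in path) {
        if (is.null(cfg)) return(default)
        cfg <- cfg[[k]]
    }
    if (is.null(cfg)) default else cfg
}

.validateConfig <- function(cfg) {
    errs <- character()
    need <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
    need(!is.null(cfg$output_dir), "output_dir: missing")
    smp <- cfg$samples
    need(!is.null(smp) && length(smp) >= 2L, "samples: need at least 2")
    nms <- vapply(smp, function(s) s$name %||% "", character(1))
    need(all(nzchar(nms)), "samples: every sample needs a name")
    need(!anyDuplicated(nms), "samples: duplicate names")
    for (s in smp) {
        src <- s$vcf %||% s$bam
        need(!is.null(src), paste0("samples/", s$name, ": needs vcf or bam"))
        if (!is.null(src))
            need(file.exists(src), paste0("samples/", s$name, ": no such file ",
                                          src))
    }
    if (any(vapply(smp, function(s) !is.null(s$bam), logical(1)))) {
        ref <- .cfgGet(cfg, c("calling", "reference"))
        need(!is.null(ref) && file.exists(ref %||% ""),
             "calling/reference: required (and must exist) when samples give BAMs")
    }
    for (grp in c("group1", "group2")) {
        need(length(cfg[[grp]]) >= 1L, paste0(grp, ": missing"))
        unknown <- setdiff(cfg[[grp]], nms)
        need(!length(unknown), paste0(grp, ": unknown sample(s) ",
                                      paste(unknown, collapse = ", ")))
    }
    for (f in c(.cfgGet(cfg, c("annotation", "bed")),
                .cfgGet(cfg, c("correlate", "expression")),
                .cfgGet(cfg, c("correlate", "pairs"))))
        if (!is.null(f)) need(file.exists(f), paste0("no such file: ", f))
    errs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the whole pipeline from a declarative config
#'
#' Validates the configuration up front (every problem is reported before
#' any computation starts), then executes the stages in dependency order:
#' methylation calling (when samples are given as BAMs), filtering, group
#' summarization, optional annotation aggregation, DMR calling, and
#' optional expression correlation.  With \code{resume = TRUE} a stage is
#' skipped when its declared outputs already exist.  A JSON manifest
#' (package version, parameters, input checksums, completed stages) is
#' written to the output directory.
#'
#' @param config a YAML file path or an equivalent nested list.  Keys:
#'   \code{output_dir}, \code{seed}, \code{samples} (list of
#'   \code{name} + \code{vcf} or \code{bam}), \code{group1}, \code{group2},
#'   and optional sections \code{calling} (\code{reference},
#'   \code{min_base_quality}, \code{min_mapping_quality}, \code{trim_ends},
#'   \code{clip_overlap}), \code{filtering} (\code{min_coverage},
#'   \code{max_coverage}, \code{contexts}), \code{summarize}
#'   (\code{min_coverage}, \code{min_samples}), \code{annotation}
#'   (\code{bed}, \code{min_positions}), \code{dmr} (the
#'   [SegmentationParams()] fields) and \code{correlate}
#'   (\code{expression}, \code{pairs}, \code{cutoff}).
#' @param resume skip stages whose outputs exist (default FALSE).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, resume = FALSE) {
    cfg <- if (is.character(config)) yaml::read_yaml(config) else config
    errs <- .validateConfig(cfg)
    if (length(errs))
        stop("configuration invalid:\n  ", paste(errs, collapse = "\n  "))
    out <- cfg$output_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    nms <- vapply(cfg$samples, `[[`, character(1), "name")
    done <- character()
    stamp <- function(stage) done <<- c(done, stage)

    # -- calling ------------------------------------------------------------
    vcfs <- setNames(vector("list", length(nms)), nms)
    call_dir <- file.path(out, "calls")
    for (s in cfg$samples) {
        if (!is.null(s$vcf)) { vcfs[[s$name]] <- s$vcf; next }
        dir.create(call_dir, showWarnings = FALSE)
        dest <- file.path(call_dir, paste0(s$name, ".vcf"))
        if (!(resume && file.exists(dest))) {
            opts <- CallingOptions(
                min_base_quality = .cfgGet(cfg, c("calling", "min_base_quality"), 20L),
                min_mapping_quality = .cfgGet(cfg, c("calling", "min_mapping_quality"), 10L),
                trim_ends = .cfgGet(cfg, c("calling", "trim_ends"), 0L),
                clip_overlap = .cfgGet(cfg, c("calling", "clip_overlap"), TRUE))
            writeMethylationVcf(
                callMethylation(s$bam, .cfgGet(cfg, c("calling", "reference")),
                                opts), dest)
        }
        vcfs[[s$name]] <- dest
    }
    if (any(vapply(cfg$samples, function(s) !is.null(s$bam), logical(1))))
        stamp("call")

    # -- filtering ----------------------------------------------------------
    filt_dir <- file.path(out, "filtered")
    dir.create(filt_dir, showWarnings = FALSE)
    spec <- FilterSpec(
        min_coverage = .cfgGet(cfg, c("filtering", "min_coverage"), 10L),
        max_coverage = .cfgGet(cfg, c("filtering", "max_coverage")),
        contexts = unlist(.cfgGet(cfg, c("filtering", "contexts"), "CG")))
    fvcfs <- setNames(file.path(filt_dir, paste0(nms, ".vcf")), nms)
    if (!(resume && all(file.exists(fvcfs)))) {
        for (nm in nms) {
            res <- filterCalls(readMethylationVcf(vcfs[[nm]]), spec)
            writeMethylationVcf(res$calls, fvcfs[[nm]])
            writeBedGraph(res$calls, file.path(filt_dir,
                                               paste0(nm, ".bedGraph")))
            write.table(res$report,
                        file.path(filt_dir, paste0(nm, "_report.tsv")),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        }
    }
    stamp("filter")

    # -- summarize ----------------------------------------------------------
    sum_dir <- file.path(out, "summarize")
    dir.create(sum_dir, showWarnings = FALSE)
    mm <- buildSampleMatrix(as.list(fvcfs), nms,
                            min_coverage = .cfgGet(cfg, c("summarize", "min_coverage"), 10L))
    gs <- summarizeGroups(mm, cfg$group1, cfg$group2,
                          min_samples = .cfgGet(cfg, c("summarize", "min_samples"), 1L))
    if (!(resume && file.exists(file.path(sum_dir, "diff.bedGraph")))) {
        writeBedGraph(gs, file.path(sum_dir, "group1_mean.bedGraph"), "mean_g1")
        writeBedGraph(gs, file.path(sum_dir, "group2_mean.bedGraph"), "mean_g2")
        writeBedGraph(gs, file.path(sum_dir, "diff.bedGraph"), "diff")
        if (ncol(mm) >= 2L && length(gs) >= 2L) {
            ov <- overviewStatistics(mm, gs)
            write.table(ov$rate_bins, file.path(sum_dir, "rate_bins.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            write.table(ov$diff_bins, file.path(sum_dir, "diff_bins.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        }
        bm <- genomewideBinnedMeans(mm,
                                    .cfgGet(cfg, c("summarize", "bin_size"), 1e6))
        write.table(bm, file.path(sum_dir, "binned_means.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    stamp("summarize")

    # -- annotation ---------------------------------------------------------
    bed <- .cfgGet(cfg, c("annotation", "bed"))
    if (!is.null(bed)) {
        ann_dir <- file.path(out, "annotation")
        dir.create(ann_dir, showWarnings = FALSE)
        if (!(resume && file.exists(file.path(ann_dir, "region_means.tsv")))) {
            agg <- aggregateOverRegions(
                mm, readBed(bed),
                min_positions = .cfgGet(cfg, c("annotation", "min_positions"), 3L),
                group1 = cfg$group1, group2 = cfg$group2)
            write.table(data.frame(name = rownames(agg$table), agg$table,
                                   check.names = FALSE),
                        file.path(ann_dir, "region_means.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            if (!is.null(agg$group_means))
                write.table(agg$group_means,
                            file.path(ann_dir, "region_group_means.tsv"),
                            sep = "\t", quote = FALSE, row.names = FALSE)
        }
        stamp("annotate")
    }

    # -- dmr ----------------------------------------------------------------
    dmr_dir <- file.path(out, "dmr")
    dir.create(dmr_dir, showWarnings = FALSE)
    dmr_bed <- file.path(dmr_dir, "dmrs.bed")
    params <- SegmentationParams(
        max_gap = .cfgGet(cfg, c("dmr", "max_gap"), 300L),
        min_cpg = .cfgGet(cfg, c("dmr", "min_cpg"), 10L),
        min_diff = .cfgGet(cfg, c("dmr", "min_diff"), 0.1),
        max_q = .cfgGet(cfg, c("dmr", "max_q"), 0.05),
        min_length_nt = .cfgGet(cfg, c("dmr", "min_length_nt")))
    if (!(resume && file.exists(dmr_bed))) {
        dmrs <- callDMRs(gs, params)
        writeBed(dmrs, dmr_bed)
        if (length(dmrs))
            writeBedGraph(dmrs, file.path(dmr_dir, "dmrs_diff.bedGraph"),
                          "mean_diff")
        dstats <- dmrStatistics(dmrs)
        for (tn in c("length_nt", "length_cpg", "abs_diff"))
            write.table(dstats[[tn]],
                        file.path(dmr_dir, paste0(tn, "_hist.tsv")),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(as.data.frame(mcols(dmrs)),
                    file.path(dmr_dir, "dmrs.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    } else {
        dmrs <- NULL
    }
    stamp("dmr")

    # -- correlate ----------------------------------------------------------
    expr_path <- .cfgGet(cfg, c("correlate", "expression"))
    if (!is.null(expr_path)) {
        cor_dir <- file.path(out, "correlate")
        dir.create(cor_dir, showWarnings = FALSE)
        if (!(resume && file.exists(file.path(cor_dir, "correlations.tsv")))) {
            if (is.null(dmrs)) dmrs <- callDMRs(gs, params)
            expr <- readExpressionTable(expr_path)
            prs <- readPairTable(.cfgGet(cfg, c("correlate", "pairs")))
            prs <- prs[prs$dmr_id %in% mcols(dmrs)$name, , drop = FALSE]
            if (nrow(prs)) {
                recs <- correlatePairs(dmrs, mm, expr, prs)
                rep <- correlationReport(
                    recs, cutoff = .cfgGet(cfg, c("correlate", "cutoff"), 0.8))
                write.table(rep$table,
                            file.path(cor_dir, "correlations.tsv"),
                            sep = "\t", quote = FALSE, row.names = FALSE)
                write.table(rep$cdmrs, file.path(cor_dir, "cdmrs.tsv"),
                            sep = "\t", quote = FALSE, row.names = FALSE)
            }
        }
        stamp("correlate")
    }

    inputs <- unlist(c(lapply(cfg$samples, function(s) s$vcf %||% s$bam),
                       .cfgGet(cfg, c("calling", "reference")), bed,
                       expr_path, .cfgGet(cfg, c("correlate", "pairs"))))
    manifest <- list(
        package = "methforge",
        version = as.character(utils::packageVersion("methforge")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        stages_completed = done,
        parameters = cfg[setdiff(names(cfg), "samples")],
        input_checksums = as.list(tools::md5sum(inputs)))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
}
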