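# A GroupSummary built directly from given per-position group means, for
# exercising the segmentation/testing machinery in isolation.
gs_from_means <- function(pos, m1, m2, chrom = "chr1") {
    n <- length(pos)
    gr <- GRanges(rep(chrom, n), IRanges(as.integer(pos), width = 1L),
                  strand = rep("+", n), context = rep("CG", n),
                  mean_g1 = m1, mean_g2 = m2, diff = m1 - m2,
                  n_covered_g1 = rep(4L, n), n_covered_g2 = rep(4L, n))
    new("GroupSummary", gr, group1 = paste0("A", 1:4),
        group2 = paste0("B", 1:4), minSamples = 3L)
}

test_that("exact Mann-Whitney equals exhaustive enumeration", {
    expect_equal(mannWhitneyU(c(0.1, 0.2, 0.3, 0.4),
                              c(0.6, 0.7, 0.8, 0.9))$p, 2 / 70)
    expect_equal(mannWhitneyU(1:4, 1:4)$p, 1)
    set.seed(77)
    for (i in 1:60) {
        n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
        # mix of continuous and heavily tied data
        if (i %% 2) { x <- runif(n1); y <- runif(n2) }
        else { x <- sample(1:3, n1, TRUE) / 4; y <- sample(1:3, n2, TRUE) / 4 }
        res <- mannWhitneyU(x, y)
        expect_identical(res$method, "exact")
        expect_equal(res$p, mwu_enum_p(x, y), tolerance = 1e-12)
    }
    # agreement with the standard implementation in the tie-free exact case
    set.seed(78)
    for (i in 1:20) {
        x <- runif(6); y <- runif(7)
        expect_equal(mannWhitneyU(x, y)$p,
                     wilcox.test(x, y, exact = TRUE)$p.value,
                     tolerance = 1e-12)
    }
})

test_that("the normal approximation tracks the exact p at moderate sizes", {
    set.seed(79)
    res <- t(replicate(200, {
        n1 <- sample(8:12, 1); n2 <- sample(8:12, 1)
        shift <- runif(1, 0, 0.6)
        x <- runif(n1); y <- runif(n2) + shift
        exact <- mannWhitneyU(x, y, exact_max = 30L)$p
        approx <- mannWhitneyU(x, y, exact_max = 0L)$p
        c(exact = exact, rel = abs(approx - exact) / exact)
    }))
    # the approximation serves sizes just past the exact-enumeration
    # switch; it is tight in the body of the distribution and, like any
    # normal tail approximation, loosens in the extreme tail
    expect_lt(median(res[, "rel"]), 0.1)
    body <- res[, "exact"] >= 0.05
    expect_gt(sum(body), 50)
    expect_lt(max(res[body, "rel"]), 0.1)
})

test_that("the 2D KS test behaves as a two-sample test should", {
    set.seed(80)
    x <- runif(30); y <- runif(30)
    same <- ks2d(x, y, x, y)
    expect_equal(same$D, 0)
    expect_equal(same$p, 1)
    # strong separation in the second coordinate
    sep <- ks2d(seq_len(30), runif(30, 0, 0.3),
                seq_len(30), runif(30, 0.7, 1))
    expect_gt(sep$D, 0.8)
    expect_lt(sep$p, 1e-4)
    # p always in (0, 1]
    for (i in 1:20) {
        n <- sample(5:40, 1)
        p <- ks2d(runif(n), runif(n), runif(n), runif(n))$p
        expect_gt(p, 0)
        expect_lte(p, 1)
    }
})

test_that("presegmentation partitions positions at chromosome and gap bounds", {
    gs <- gs_from_means(c(100, 200, 900), rep(0.5, 3), rep(0.5, 3))
    runs <- presegment(gs, 300)
    expect_identical(unname(lapply(runs, as.integer)), list(1:2, 3L))

    expect_identical(presegment(gs_from_means(integer(), numeric(),
                                              numeric()), 300), list())

    set.seed(81)
    pos <- sort(sample(1e6, 1000))
    gs <- gs_from_means(pos, runif(1000), runif(1000))
    runs <- presegment(gs, 300)
    # brute-force gap scan
    brk <- c(TRUE, diff(pos) > 300)
    expect_identical(unname(lapply(runs, as.integer)),
                     unname(split(seq_along(pos), cumsum(brk))))
    expect_identical(sort(unname(unlist(runs))), seq_along(pos))
})

test_that("a noise-free planted segment is recovered exactly", {
    d <- rep(0, 30); d[11:20] <- 0.5
    m1 <- rep(0.4, 30) + d / 2; m2 <- rep(0.4, 30) - d / 2
    gs <- gs_from_means(seq(100, by = 50, length.out = 30), m1, m2)
    best <- methforge:::.maxMeanSegment(groupDiff(gs), 10L)
    expect_identical(c(best$i, best$j), c(11L, 20L))
    # constant zero difference yields nothing past the min_diff filter
    gs0 <- gs_from_means(seq(100, by = 50, length.out = 30),
                         rep(0.4, 30), rep(0.4, 30))
    expect_length(callDMRs(gs0), 0)
})

test_that("noisy planted segments are located within two positions", {
    set.seed(82)
    hits <- replicate(100, {
        n <- 40
        d <- rep(0, n); d[16:25] <- 0.5
        base <- runif(n, 0.25, 0.75)
        noise <- function() rnorm(n, 0, 0.05)
        m1 <- pmin(1, pmax(0, base + d / 2 + noise()))
        m2 <- pmin(1, pmax(0, base - d / 2 + noise()))
        best <- methforge:::.maxMeanSegment(m1 - m2, 10L)
        abs(best$i - 16) <= 2 && abs(best$j - 25) <= 2
    })
    expect_gte(mean(hits), 0.9)
})

test_that("degenerate and identical regions test as null", {
    gs <- gs_from_means(1:10 * 100, rep(0.3, 10), rep(0.3, 10))
    tr <- testRegion(gs, 1:10)
    expect_true(tr$degenerate)
    expect_equal(tr$p_mwu, 1)
})

test_that("group swap maps DMRs to identical intervals with negated diff", {
    set.seed(83)
    sim <- simulateCaseControl(chrom_length = 1e5, n_dmrs = 6L, seed = 83)
    mm <- sim$matrix
    fwd <- summarizeGroups(mm, sim$group1, sim$group2, min_samples = 3L)
    rev <- summarizeGroups(mm, sim$group2, sim$group1, min_samples = 3L)
    d1 <- callDMRs(fwd)
    d2 <- callDMRs(rev)
    expect_gt(length(d1), 0)
    expect_identical(start(d1), start(d2))
    expect_identical(end(d1), end(d2))
    expect_equal(mcols(d1)$mean_diff, -mcols(d2)$mean_diff)
    expect_equal(mcols(d1)$p_mwu, mcols(d2)$p_mwu)
    expect_equal(mcols(d1)$p_ks2d, mcols(d2)$p_ks2d)
    expect_equal(mcols(d1)$q, mcols(d2)$q)
    expect_identical(mcols(d1)$direction == "hyper",
                     mcols(d2)$direction == "hypo")
})

test_that("tightening filters never adds DMRs; BH q-values are coherent", {
    set.seed(84)
    sim <- simulateCaseControl(chrom_length = 1e5, n_dmrs = 6L, seed = 84)
    gs <- sim$summary
    base <- callDMRs(gs, SegmentationParams(min_diff = 0.05, max_q = 0.2))
    for (params in list(SegmentationParams(min_diff = 0.2, max_q = 0.2),
                        SegmentationParams(min_diff = 0.05, max_q = 0.01),
                        SegmentationParams(min_diff = 0.05, max_q = 0.2,
                                           min_length_nt = 500))) {
        tighter <- callDMRs(gs, params)
        expect_lte(length(tighter), length(base))
        expect_true(all(mcols(tighter)$name %in% paste0("DMR_",
                        seq_len(length(base) + 50))))
        # every reported DMR honours its own contract
        mc <- mcols(tighter)
        expect_true(all(mc$q <= params$max_q))
        expect_true(all(abs(mc$mean_diff) >= params$min_diff))
        expect_true(all(mc$n_cpg >= params$min_cpg))
        if (!is.null(params$min_length_nt))
            expect_true(all(width(tighter) >= params$min_length_nt))
    }
    # BH: q in [p, 1], monotone in p-rank, equals p.adjust
    cand <- S4Vectors::metadata(base)$candidates
    expect_equal(cand$q, p.adjust(cand$p_mwu, "BH"))
    expect_true(all(cand$q >= cand$p_mwu - 1e-12))
    expect_true(all(cand$q <= 1))
    o <- order(cand$p_mwu)
    expect_true(all(diff(cand$q[o]) >= -1e-12))
})

test_that("single candidate yields q = p (degenerate BH)", {
    set.seed(85)
    d <- rep(0, 12); d[2:11] <- 0.6
    base <- runif(12, 0.2, 0.4)
    m1 <- pmin(1, base + d / 2); m2 <- pmax(0, base - d / 2)
    gs <- gs_from_means(1:12 * 50, m1, m2)
    dmrs <- suppressMessages(callDMRs(gs, SegmentationParams(min_cpg = 10L)))
    cand <- S4Vectors::metadata(dmrs)$candidates
    if (nrow(cand) == 1L) expect_equal(cand$q, cand$p_mwu)
})

test_that("DMR statistics tables tally every region exactly once", {
    expect_identical(nrow(dmrStatistics(callDMRs(gs_from_means(
        1:3 * 1000, rep(0.1, 3), rep(0.1, 3))))$length_nt), 0L)

    set.seed(86)
    sim <- simulateCaseControl(chrom_length = 1e5, n_dmrs = 6L, seed = 86)
    dmrs <- callDMRs(sim$summary)
    st <- dmrStatistics(dmrs)
    expect_identical(sum(st$length_nt$n), length(dmrs))
    expect_identical(sum(st$length_cpg$n), length(dmrs))
    expect_identical(sum(st$abs_diff$n), length(dmrs))
    expect_identical(nrow(st$scatter_means), length(dmrs))
    expect_equal(st$scatter_diff_q$q, mcols(dmrs)$q)
})
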