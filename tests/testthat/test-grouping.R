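make_sample <- function(pos, rates, cov = 20L, chrom = "chr1") {
    nm <- as.integer(round(rates * cov))
    make_calls(chrom, pos, "+", "CG", nm, cov - nm)
}

test_that("the sample matrix holds the union of positions with explicit missingness", {
    s1 <- make_sample(c(10L, 20L, 30L), c(0.1, 0.5, 0.9))
    mm <- buildSampleMatrix(list(A = s1), min_coverage = 10L)
    expect_identical(dim(mm), c(3L, 1L))
    expect_equal(as.numeric(methRate(mm)), c(0.1, 0.5, 0.9))

    s2 <- make_sample(c(40L, 50L), c(0.2, 0.4))
    mm <- buildSampleMatrix(list(A = s1, B = s2), min_coverage = 10L)
    expect_identical(nrow(mm), 5L)
    expect_identical(sum(is.na(methRate(mm))), 5L)

    # below-threshold coverage is missing, not zero
    s3 <- make_calls("chr1", 10L, "+", "CG", 1L, 2L)  # coverage 3
    mm <- buildSampleMatrix(list(A = s1, C = s3), min_coverage = 10L)
    expect_true(is.na(methRate(mm)[1, "C"]))
    expect_identical(unname(methCoverage(mm)[1, "C"]), 3L)

    expect_error(buildSampleMatrix(list(A = s1, A = s1)), "duplicate")
})

test_that("matrix assembly matches a brute-force layout for 8 samples", {
    set.seed(21)
    samples <- lapply(1:8, function(i) {
        pos <- sort(sample(seq(10L, 5000L, by = 10L), 150))
        cov <- rpois(150, 20) + 1L
        nm <- rbinom(150, cov, 0.5)
        make_calls("chr1", pos, "+", "CG", nm, cov - nm)
    })
    names(samples) <- paste0("S", 1:8)
    mm <- buildSampleMatrix(samples, min_coverage = 10L)
    all_pos <- sort(unique(unlist(lapply(samples, start))))
    expect_identical(start(rowRanges(mm)), all_pos)
    for (s in c(1, 5, 8)) {
        x <- samples[[s]]
        for (p in c(all_pos[1], all_pos[37], all_pos[length(all_pos)])) {
            i <- which(all_pos == p); j <- which(start(x) == p)
            if (!length(j)) {
                expect_true(is.na(methRate(mm)[i, s]))
            } else if (methCoverage(x)[j] >= 10) {
                expect_identical(unname(methRate(mm)[i, s]), methRate(x)[j])
            } else {
                expect_true(is.na(methRate(mm)[i, s]))
            }
        }
    }
})

test_that("group summaries respect min_samples and are antisymmetric", {
    s <- lapply(1:4, function(i)
        make_sample(c(10L, 20L, 30L, 40L), c(0.8, 0.7, 0.2, 0.9)))
    t <- lapply(1:4, function(i)
        make_sample(c(10L, 20L, 30L, 40L), c(0.2, 0.3, 0.2, 0.5)))
    names(s) <- paste0("A", 1:4); names(t) <- paste0("B", 1:4)
    mm <- buildSampleMatrix(c(s, t), min_coverage = 10L)
    gs <- summarizeGroups(mm, names(s), names(t), min_samples = 3L)
    expect_equal(groupDiff(gs), c(0.6, 0.4, 0.0, 0.4))
    swapped <- summarizeGroups(mm, names(t), names(s), min_samples = 3L)
    expect_identical(groupDiff(swapped), -groupDiff(gs))
    expect_identical(start(swapped), start(gs))

    expect_error(summarizeGroups(mm, names(s), names(t), min_samples = 5L),
                 "min_samples")
    expect_error(summarizeGroups(mm, names(s), c("B1", "A1"), 1L), "disjoint")

    # single-sample groups: mean is the sample's rate
    gs1 <- summarizeGroups(mm, "A1", "B1", min_samples = 1L)
    expect_equal(groupMeans(gs1)[, 1], methRate(mm)[, "A1"])
})

test_that("min_samples retention matches brute-force evaluation under planted missingness", {
    set.seed(33)
    pos <- seq(10L, 2000L, by = 10L)
    samples <- lapply(1:8, function(i) {
        keep <- runif(length(pos)) > 0.3   # plant missingness
        p <- pos[keep]
        cov <- rpois(length(p), 30) + 10L
        nm <- rbinom(length(p), cov, 0.5)
        make_calls("chr1", p, "+", "CG", nm, cov - nm)
    })
    names(samples) <- paste0("S", 1:8)
    mm <- buildSampleMatrix(samples, min_coverage = 10L)
    gs <- summarizeGroups(mm, paste0("S", 1:4), paste0("S", 5:8),
                          min_samples = 3L)
    r <- methRate(mm)
    n1 <- rowSums(!is.na(r[, 1:4])); n2 <- rowSums(!is.na(r[, 5:8]))
    expect_identical(start(gs), start(rowRanges(mm))[n1 >= 3 & n2 >= 3])
    expect_true(all(mcols(gs)$n_covered_g1 >= 3))
    expect_true(all(mcols(gs)$n_covered_g2 >= 3))
})

test_that("overview statistics: clustering separates strong group structure", {
    set.seed(44)
    pos <- seq(10L, 3000L, by = 10L)
    base <- runif(length(pos), 0.2, 0.4)
    mk <- function(shift) {
        r <- pmin(1, pmax(0, base + shift + rnorm(length(pos), 0, 0.03)))
        cov <- rep(30L, length(pos))
        make_calls("chr1", pos, "+", "CG", as.integer(round(r * cov)),
                   cov - as.integer(round(r * cov)))
    }
    g1 <- lapply(1:4, function(i) mk(0))
    g2 <- lapply(1:4, function(i) mk(0.4))
    names(g1) <- paste0("ctrl", 1:4); names(g2) <- paste0("case", 1:4)
    mm <- buildSampleMatrix(c(g1, g2), min_coverage = 10L)
    gs <- summarizeGroups(mm, names(g1), names(g2), min_samples = 3L)
    ov <- overviewStatistics(mm, gs)
    # distance matrix is symmetric, zero-diagonal
    expect_identical(ov$dist, t(ov$dist))
    expect_true(all(diag(ov$dist) == 0))
    # two top-level clades = the two groups
    top <- cutree(ov$hclust, k = 2)
    expect_length(unique(top[names(g1)]), 1)
    expect_length(unique(top[names(g2)]), 1)
    expect_false(top[["ctrl1"]] == top[["case1"]])
    # bin counts conserve positions
    expect_identical(sum(ov$rate_bins$n_g1), length(gs))
    expect_identical(sum(ov$diff_bins$n), length(gs))
    # diff concentrated away from 0 here; a null summary concentrates at 0
    gs0 <- summarizeGroups(mm, names(g1)[1:2], names(g1)[3:4],
                           min_samples = 1L)
    ov0 <- overviewStatistics(mm[, names(g1)], gs0)
    zero_bin <- which(ov0$diff_bins$bin_lo <= 0 & ov0$diff_bins$bin_hi > 0)
    expect_gt(ov0$diff_bins$n[zero_bin] / sum(ov0$diff_bins$n), 0.5)
})

test_that("identical samples are merged first at distance zero", {
    s <- make_sample(c(10L, 20L, 30L), c(0.1, 0.5, 0.9))
    mm <- buildSampleMatrix(list(X = s, Y = s, Z = make_sample(
        c(10L, 20L, 30L), c(0.9, 0.1, 0.2))), min_coverage = 10L)
    gs <- summarizeGroups(mm, c("X", "Y"), "Z", min_samples = 1L)
    ov <- overviewStatistics(mm, gs)
    expect_identical(ov$dist["X", "Y"], 0)
    expect_identical(sort(ov$hclust$labels[abs(ov$hclust$merge[1, ])]),
                     c("X", "Y"))
})

test_that("genome-wide binned means equal brute-force binning", {
    empty_mm <- suppressWarnings(
        buildSampleMatrix(list(A = MethylationCalls())))
    expect_identical(nrow(genomewideBinnedMeans(empty_mm)), 0L)

    s1 <- make_sample(c(100L, 900L, 1500L), c(0.2, 0.4, 0.8))
    mm <- buildSampleMatrix(list(A = s1), min_coverage = 10L)
    bm <- genomewideBinnedMeans(mm, bin_size = 1000)
    expect_identical(nrow(bm), 2L)
    expect_equal(bm$A, c(mean(c(0.2, 0.4)), 0.8))
    expect_identical(bm$bin_start, c(0, 1000))

    set.seed(55)
    pos <- sort(sample(1:50000, 400))
    samples <- lapply(1:3, function(i) {
        cov <- rpois(400, 20) + 10L
        nm <- rbinom(400, cov, 0.5)
        make_calls("chr1", pos, "+", "CG", nm, cov - nm)
    })
    names(samples) <- c("A", "B", "C")
    mm <- buildSampleMatrix(samples, min_coverage = 10L)
    bm <- genomewideBinnedMeans(mm, bin_size = 5000)
    r <- methRate(mm)
    for (k in sample(nrow(bm), 5)) {
        inbin <- start(rowRanges(mm)) > bm$bin_start[k] &
                 start(rowRanges(mm)) <= bm$bin_end[k]
        expect_equal(bm$B[k], mean(r[inbin, "B"], na.rm = TRUE))
    }
})
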