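test_that("the simulated reference honours seed and CpG density", {
    a <- simulateReference(1L, 5000L, 0.02, seed = 5)
    b <- simulateReference(1L, 5000L, 0.02, seed = 5)
    expect_identical(as.character(a$sequences), as.character(b$sequences))
    expect_identical(a$cytosines, b$cytosines)

    none <- simulateReference(1L, 2000L, 0, seed = 6)
    expect_identical(
        gregexpr("CG", as.character(none$sequences[[1]]))[[1]][1], -1L)

    dense <- simulateReference(1L, 10000L, 0.05, seed = 7)
    n_cg <- length(gregexpr("CG", as.character(dense$sequences[[1]]))[[1]])
    expected <- 0.05 * 9999
    expect_lt(abs(n_cg - expected), 3 * sqrt(expected) + 0.05 * expected)

    # context map agrees with the classifier applied to the sequence
    s <- as.character(dense$sequences[[1]])
    cyt <- dense$cytosines
    pick <- cyt[sample(nrow(cyt), 200), ]
    expect_identical(classifyContext(s, pick$pos, pick$strand), pick$context)
})

test_that("planted truth obeys its own geometry", {
    ref <- simulateReference(1L, 2e5, 0.01, seed = 8)
    truth <- simulateTruth(ref, n_dmrs = 15L, dmr_n_cpg = 10L, delta = 0.5,
                           seed = 8)
    pd <- truth$planted_dmrs
    expect_identical(nrow(pd), 15L)
    # non-overlapping
    o <- order(pd$start)
    expect_true(all(pd$start[o][-1] > pd$end[o][-nrow(pd)]))
    # each spans exactly 10 forward CpG sites with bounded gaps
    cg <- truth$positions[truth$positions$context == "CG" &
                          truth$positions$strand == "+", ]
    for (k in sample(15, 5)) {
        sites <- cg$pos[cg$pos >= pd$start[k] & cg$pos < pd$end[k]]
        expect_length(sites, 10)
        expect_true(all(diff(sites) <= 300))
    }
    # rates differ by delta (pre-clamp) only inside planted regions
    inside <- truth$positions$in_dmr
    expect_true(all(truth$positions$rate_g1[!inside] ==
                    truth$positions$rate_g2[!inside]))
    expect_true(all(abs(truth$positions$rate_g1[inside] -
                        truth$positions$rate_g2[inside]) > 0))
})

test_that("beta-binomial counts match closed-form moments", {
    ref <- simulateReference(1L, 1000L, 0.01, seed = 9)
    rho <- 0.1; p_true <- 0.3; covn <- 40L
    n <- 5000
    truth <- structure(list(
        positions = data.frame(chrom = "chr1", pos = seq_len(n) * 10L,
                               strand = "+", context = "CG",
                               base_rate = p_true, rate_g1 = p_true,
                               rate_g2 = p_true, in_dmr = FALSE),
        dispersion = rho, planted_dmrs = NULL), class = "SimulationTruth")
    # fixed coverage via a degenerate Poisson is not available; use the
    # moments of n_meth conditional on the realized coverages instead
    smp <- simulateCounts(truth, n_per_group = 1L, mean_coverage = covn,
                          seed = 9)
    x <- smp$S1
    cov <- methCoverage(x); nm <- nMeth(x)
    # E[nm | cov] = cov * p ; pooled z-test on the mean rate
    expect_lt(abs(mean(nm) - mean(cov) * p_true),
              4 * sqrt(sum(cov * p_true * (1 - p_true) *
                           (1 + (cov - 1) * rho))) / length(cov))
    # Var[nm | cov] = cov p (1-p) (1 + (cov-1) rho): compare at one coverage
    at <- cov == covn
    v_obs <- var(nm[at])
    v_exp <- covn * p_true * (1 - p_true) * (1 + (covn - 1) * rho)
    expect_lt(abs(v_obs - v_exp), 4 * v_exp * sqrt(2 / sum(at)))

    # dispersion 0, huge coverage: empirical rate converges to truth
    truth0 <- truth; truth0$dispersion <- 0
    truth0$positions <- truth0$positions[1:50, ]
    smp0 <- simulateCounts(truth0, 1L, 10000, seed = 10)
    expect_lt(max(abs(methRate(smp0$S1) - p_true)), 0.01)
})

test_that("null truth yields group means differing only by noise", {
    ref <- simulateReference(1L, 5e4, 0.01, seed = 11)
    truth <- simulateTruth(ref, n_dmrs = 0L, seed = 11)
    smp <- simulateCounts(truth, 4L, 30, contexts = "CG", seed = 11)
    mm <- buildSampleMatrix(smp, names(smp), min_coverage = 10L)
    gs <- summarizeGroups(mm, names(smp)[1:4], names(smp)[5:8], 3L)
    expect_lt(abs(mean(groupDiff(gs))), 0.01)
    expect_lt(quantile(abs(groupDiff(gs)), 0.99), 0.35)
})

test_that("read simulation round-trips through calling at the binary limit", {
    ref <- simulateReference(1L, 4000L, 0.02, seed = 12)
    truth <- simulateTruth(ref, n_dmrs = 0L, seed = 12)
    truth$positions$rate_g1 <- as.numeric(truth$positions$base_rate > 0.5)
    bam <- simulateReads(ref, truth, n_fragments = 800L, error_rate = 0,
                         conversion_rate = 1,
                         out = file.path(tempfile("reads"), "sim.bam"),
                         seed = 12)
    calls <- callMethylation(bam, ref$sequences,
                             CallingOptions(min_base_quality = 0))
    key <- paste0(truth$positions$chrom, ":", truth$positions$pos)
    tr <- truth$positions$rate_g1[
        match(paste0(seqnames(calls), ":", start(calls)), key)]
    expect_gt(length(calls), 100)
    expect_identical(methRate(calls), tr)

    # all-zero truth: everything converts, rate 0 everywhere
    truth$positions$rate_g1 <- 0
    bam0 <- simulateReads(ref, truth, n_fragments = 200L, error_rate = 0,
                          conversion_rate = 1,
                          out = file.path(tempfile("reads"), "sim0.bam"),
                          seed = 13)
    calls0 <- callMethylation(bam0, ref$sequences,
                              CallingOptions(min_base_quality = 0))
    expect_true(all(methRate(calls0) == 0))
})

test_that("intermediate rates are recovered within binomial error", {
    ref <- simulateReference(1L, 3000L, 0.02, seed = 14)
    truth <- simulateTruth(ref, n_dmrs = 0L, seed = 14)
    truth$positions$rate_g1 <- 0.5
    bam <- simulateReads(ref, truth, n_fragments = 6000L,
                         fragment_length = 200L,
                         out = file.path(tempfile("reads"), "sim5.bam"),
                         seed = 14)
    calls <- callMethylation(bam, ref$sequences,
                             CallingOptions(min_base_quality = 0))
    deep <- calls[methCoverage(calls) >= 100]
    expect_gt(length(deep), 20)
    # pooled estimate is extremely tight; per-site within binomial CI
    pooled <- sum(nMeth(deep)) / sum(methCoverage(deep))
    expect_lt(abs(pooled - 0.5), 0.02)
    ci_ok <- abs(methRate(deep) - 0.5) <=
        3 * sqrt(0.25 / methCoverage(deep))
    expect_gt(mean(ci_ok), 0.98)
})

test_that("expression links carry the planted sign and tighten as noise vanishes", {
    sim <- simulateCaseControl(chrom_length = 1e5, n_dmrs = 8L,
                               noise_sd = 0, seed = 15)
    expect_false(is.null(sim$expression))
    links <- sim$truth$expression_links
    dmrs_gr <- GRanges(sim$truth$planted_dmrs$chrom,
                       IRanges(sim$truth$planted_dmrs$start,
                               sim$truth$planted_dmrs$end))
    r <- methRate(sim$matrix)
    for (k in seq_len(nrow(links))) {
        rows <- queryHits(findOverlaps(rowRanges(sim$matrix),
                                       dmrs_gr[links$dmr[k]]))
        meth <- colMeans(r[rows, , drop = FALSE], na.rm = TRUE)
        rr <- cor(meth, sim$expression[links$gene_id[k], colnames(sim$matrix)])
        expect_equal(abs(rr), 1, tolerance = 1e-9)
        expect_identical(sign(rr), links$sign[k])
    }
    # unlinked genes: no systematic correlation
    sims <- vapply(sim$truth$unlinked_genes, function(g) {
        rows <- queryHits(findOverlaps(rowRanges(sim$matrix), dmrs_gr[1]))
        meth <- colMeans(r[rows, , drop = FALSE], na.rm = TRUE)
        cor(meth, sim$expression[g, colnames(sim$matrix)])
    }, numeric(1))
    expect_lt(mean(abs(sims)), 0.8)
})
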