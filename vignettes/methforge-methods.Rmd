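---
title: "Methods and design of the methforge pipeline"
author: "methforge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the methforge pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

Bisulfite treatment converts unmethylated cytosines to uracil, read as
thymine after amplification, while 5-methylcytosine is protected.  After
alignment of the converted reads, methylation is therefore read out as a
C-versus-T contrast at reference cytosines: at a cytosine with `n_meth`
reads carrying C and `n_unmeth` reads carrying T, the methylation level is

    rate = n_meth / (n_meth + n_unmeth).

Reads derive from one of the two converted strands.  On the original-top
(CT) strand the informative positions are forward-reference cytosines; on
the original-bottom (GA) strand they are reference guanines, i.e.
cytosines of the reverse strand, which appear as G (methylated) or A
(converted) in forward-reference orientation.  `callMethylation()` assigns
each alignment to a conversion strand from the aligner's `XG` tag when
present, otherwise from read orientation under the directional protocol
(forward read 1 or reverse read 2 sequence the top strand).

Bases are excluded when below the base-quality or mapping-quality
thresholds (defaults 20 and 10 -- conventional screening values, exposed as
options), within `trim_ends` bases of a read end (a blunt but
dependency-free mitigation of end-of-read M-bias), or in the overlapping
portion of a properly paired mate.  Overlap clipping is internal rather
than delegated to an external tool: within an overlap the base of the mate
with the higher base quality is counted, ties going to read 1, which makes
the output deterministic.  Bases inside deletions contribute nothing,
soft-clipped bases are ignored, and secondary, supplementary and
duplicate-flagged alignments are skipped for calling (secondary alignments
still enter the multiplicity histogram of `mappingStatistics()`).

Sequence context (`CG`, `CHG`, `CHH`, with H = A, C or T) is classified
from the two bases following the cytosine in reading direction,
reverse-complemented for minus-strand cytosines; positions whose context
cannot be resolved (sequence end, ambiguous base) are not called.

## Filtering

Positions with low coverage carry noisy rate estimates; extremely high
coverage usually flags collapsed repeats or PCR stacks.  `filterCalls()`
keeps a record iff `min_coverage <= coverage <= max` and the context is
among the requested ones (default CG only, the dominant methylated context
in mammals).  The upper bound defaults to the 99.9th percentile of the
input's own coverage distribution, so it adapts to library depth; an
absolute cap can be given instead.  Both bounds are inclusive, filtering
with an absolute cap is idempotent, and raising `min_coverage` can only
shrink the survivor set -- all of which the test suite checks exhaustively.

Rate histograms use 100 bins over [0, 1], left-closed and right-open
except the final bin [0.99, 1], which is closed so that fully methylated
positions are counted.  Bin edges are computed as `(0:100)/100` rather
than with `seq(by = 0.01)`: the two constructions differ in the last
floating-point ulp, and the division form makes a rate that equals a bin
edge land in the mathematically correct bin.

Symmetric CpG strand merging (`destrandCpG()`) is provided but off by
default: a rate of a single strand is a legitimate observation, and
keeping strands separate preserves the ability to detect strand-specific
artifacts.  The merge sums the counts of the C at position p and the G at
p+1.

## Groups and summaries

`buildSampleMatrix()` forms the union of positions across samples and
stores rate and coverage per (position, sample).  A sample's rate is
explicitly missing (`NA`) below the per-sample coverage threshold
(default 10); missingness is never encoded as 0 because a rate of 0 is a
biological observation.  `summarizeGroups()` retains positions where each
group has at least `min_samples` covered samples and reports unweighted
arithmetic group means and their difference.  Unweighted (rather than
coverage-weighted) means keep every retained sample equally influential;
coverage weighting is a possible variant but would let one deep library
dominate a group.  Swapping the groups negates every difference exactly,
and the tests assert this as an identity, not approximately.

Sample clustering uses complete linkage on Euclidean distances computed
over the positions shared (non-missing) by each sample pair.  This choice
is deterministic and needs no imputation; pairs sharing fewer than two
positions get an undefined distance and are excluded with a warning.  The
same metric and linkage order the rows and columns of the annotation
heatmap, so the two views are comparable.

`aggregateOverRegions()` scores each annotation region independently (a
position may serve several overlapping regions) and requires
`min_positions` (default 3) contributing positions per cell -- a one-CpG
"region mean" is noise-dominated.  Interval overlap uses BED's 0-based
half-open convention throughout; the readers and writers convert exactly
and reversibly, which the round-trip tests pin down with boundary
fixtures.

## DMR detection

The caller works on the per-position group difference signal of a
two-group summary.

1.  **Pre-segmentation.**  Positions are split into runs bounded by
    `max_gap` (default 300 bp, a common linkage distance for WGBS
    screens); no reported region ever spans a gap larger than this.
2.  **Segmentation.**  Within a run, the candidate at each level is the
    sub-interval of at least `min_cpg` positions maximizing the circular
    binary segmentation contrast

        |mean(d[seg]) - mean(d[rest])| / sqrt(1/n_seg + 1/n_rest),

    i.e. the variance-normalized deviation of the segment's mean
    difference from the rest of the window.  The normalization matters: an
    unnormalized `|mean(seg)|` criterion always prefers the shortest
    allowed high-mean core of a truly uniform block and fractures it.
    The contrast is exactly symmetric between an edge segment and its
    complement, so ties are broken toward the side whose mean deviates
    more from the window mean (the side that actually changed), then
    leftmost, then shortest -- making the output deterministic.  On a
    linear signal this exhaustive sub-interval search is equivalent to the
    circular formulation's arc search.
3.  **Recursion gate.**  The split is accepted, and recursion descends
    into the selected segment and its flanks, while the two-dimensional
    Kolmogorov-Smirnov p-value of the selected segment improves on its
    parent window's; windows that stop improving are emitted as terminal
    candidates.  Because this gate is noisy, index-adjacent candidates
    with same-sign mean differences both at least `min_diff` are merged
    back into one candidate *before* any testing, so a fractured uniform
    region is reassembled without touching the correction's semantics.
4.  **Testing.**  Each candidate receives a two-sided Mann-Whitney U p
    comparing the per-position group-mean vectors, and a two-dimensional
    KS p on the point sets (position rank, group mean).  The MWU p is
    exact -- by a subset-sum dynamic program over the doubled midranks,
    equivalent to enumerating all `choose(n1+n2, n1)` assignments, ties
    included -- whenever the combined size is at most 20, and a
    tie-corrected, continuity-corrected normal approximation beyond.  The
    approximation is within a few percent of the exact value in the body
    of the distribution (all instances with exact p >= 0.05 in the test
    sweep are within 10%) and, like every normal tail approximation,
    loosens in the extreme tail; the exact path covers the sizes where
    single-instance p-values are coarse.  The 2D-KS statistic is the
    largest quadrant difference around every data point, averaged between
    the two samples' origins, with the classical effective-n and
    correlation-adjusted asymptotic tail formula.
5.  **Correction and filtering.**  One designated test keeps the FDR
    semantics clean: Benjamini-Hochberg runs over the Mann-Whitney
    p-values of *all* tested candidates genome-wide (the 2D-KS p is
    reported alongside).  Reported DMRs satisfy `q <= max_q`,
    `|mean_diff| >= min_diff`, `n_cpg >= min_cpg`, and the optional
    length bound, and are named `DMR_<k>` in sort order with direction
    hyper/hypo relative to group 1.

Defaults (`max_gap` 300, `min_cpg` 10, `min_diff` 0.1, `max_q` 0.05) are
the de-facto standards for WGBS DMR screens; all are overridable.

## DMR-expression correlation

For each user-supplied DMR-gene pair, a sample's DMR methylation is the
mean of its rates over the DMR's positions (missing below two covered
positions), and both Pearson's r and Spearman's rho are computed over the
samples with both values.  Spearman is the "non-linear" coefficient
because it is the standard monotone-invariant choice.  Pairs with fewer
than three usable samples or a zero-variance vector are flagged and their
coefficients withheld rather than propagated as NaN.  A pair is a cDMR
when the larger absolute coefficient reaches the cutoff (default 0.8, a
deliberate strictness for n as small as 8); anticorrelation counts, since
promoter methylation typically represses expression.  No p-values are
attached by default -- with typical sample counts they would be
theatrical.

## The synthetic-data generator

The generator exists so that every stage can be exercised against known
truth; its defaults are the package's reference study conditions and are
not adjusted per analysis: two groups of four samples (a small
case-control design), mean coverage 30, CpG density 0.01 per position
(human-like), beta-binomial overdispersion rho = 0.05 (typical WGBS),
planted differences delta = 0.5 across 10 consecutive CpG sites.

*Reference sequences* draw background bases uniformly, destroy every
accidental CG dinucleotide, then plant CpGs by independent Bernoulli
draws, so the realized CpG count is binomial with known expectation and a
density of zero provably yields no CpGs.  The emitted cytosine map is, by
construction, consistent with `classifyContext()` on the sequence, and a
test asserts that cross-module identity.

*True rates* are bimodal Beta(0.3, 0.3) at CpG sites -- the canonical
two-mode shape of a methylome -- and low (Beta(0.1, 1.9)) at non-CpG
cytosines.  Both strands of a CpG share one rate.  Planted DMRs occupy 10
consecutive forward CpG sites whose spacing stays within 300 bp; real DMRs
concentrate in CpG-dense regulatory regions, and a "region" interrupted by
a CpG void larger than the caller's linkage distance is not contiguous in
the tested signal under any definition.  Inside a DMR the baseline is
intermediate (Beta(5, 5)), again mirroring regulatory regions, and the two
groups sit at baseline +/- delta/2, clamped to [0, 1].

*Counts* are coverage ~ Poisson(mean), methylated reads ~ beta-binomial
with Var = n p (1-p) (1 + (n-1) rho); the closed-form moments make the
generator itself testable, and the moment tests run at 3-4 standard
errors.  *Reads* are paired-end fragments assigned to a conversion strand
with probability 1/2, methylation sampled per fragment per cytosine,
conversion applied to unmethylated cytosines, emitted as a sorted indexed
BAM with correct flags, mates, NM and XG tags.  With error rate 0,
conversion 1 and binary true rates, call -> filter -> summarize reproduces
the truth exactly -- the end-to-end identity the acceptance suite asserts.
*Expression* for linked genes is an affine function of the sample's DMR
methylation (slope sign = planted sign, baseline 20, slope magnitude 10,
Gaussian noise) and independent for unlinked genes.

What the generator does not emulate: M-bias profiles, adapter
contamination, realistic error spectra, copy-number or mapping artifacts,
and spatial correlation of methylation beyond the planted blocks.  Tests
passing on these simulations therefore demonstrate algorithmic
correctness and calibration under the stated model, not robustness to
every artifact of real libraries.

## Calibration checks and problem sizes

The suite's calibration checks run at sizes chosen to finish in minutes on
one core while keeping the statistics meaningful: the null
false-discovery check pools candidates from 50 replicates of ~10,000 CpG
records (4 vs 4, coverage 30, no planted difference, `min_diff` disabled
so only the statistical control is measured) and requires the pooled
false-discovery proportion at q <= 0.05 to stay within binomial error of
0.05 -- under a global null the per-discovery FDR is degenerate (0 or 1),
so the pooled proportion over candidates is the quantity that is actually
estimable.  The recovery benchmark plants 20 DMRs (delta 0.5, 10 CpGs) on
a 200 kb genome and requires recall and precision of at least 0.9 with
boundaries within 2 CpG sites for at least 90% of recovered regions.

## Degenerate inputs and edge policies

Empty inputs flow through as empty outputs with zeroed reports, never
errors, except where a computation is undefined (clustering fewer than two
samples, aggregating over an empty region file).  Zero-coverage positions
are unrepresentable by construction -- their rate would be undefined.  A
candidate with zero variance in both groups and zero difference tests at
p = 1, flagged.  With fewer than two candidates the BH correction
degenerates to q = p, noted in a message.  All randomness flows through
explicit integer seeds, and identical seeds give byte-identical non-plot
outputs across runs, which the pipeline test asserts file by file.

## Known limitations

- The VCF dialect is a minimal, self-contained format with counts in
  INFO; it does not claim byte compatibility with any other tool's
  VCF-style output, nor full VCF 4.x compliance.
- The 2D-KS p-value is asymptotic; for very small candidates it is a
  screening heuristic (the designated primary test for correction is the
  Mann-Whitney p, which is exact there).
- Two-group designs only; no covariates, no single-CpG testing.
- DMR-gene associations are an input; the package does not assign genes
  to DMRs.
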