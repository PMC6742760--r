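---
title: "Models and methods behind hicstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hicstates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hicstates)
```

`hicstates` implements a comparative 3D-epigenome analysis across cell
lines — typically one normal line and two cancer lines — from binned Hi-C
contact matrices, histone-mark and CTCF peak sets, nucleosome-depleted
regions (NDRs), and RNA-seq expression tables. This vignette explains the
statistical models, the numerical choices, what the synthetic-data generator
does and does not emulate, and the known limitations. All coordinates in the
package are 0-based half-open (the BED convention); any 1-based format is
converted at the file boundary.

## Matrix balancing (ICE)

Raw binned Hi-C counts carry strong multiplicative per-bin biases
(mappability, GC, fragment density). We model the raw count for bins $i,j$
as $x_{ij} \sim \mathrm{Poisson}(b_i\,b_j\,\lambda_{ij})$ and remove the
bias by iterative proportional fitting: repeat
$b_i \leftarrow b_i \cdot m_i/\bar m$, where $m_i$ is the current row
marginal, until the maximum relative marginal deviation falls below `tol`.
Defaults are `tol = 1e-4` and `max_iter = 200`, the common practice for
matrices of this size; convergence is typically reached in a few dozen
iterations. Bins whose raw marginal lies strictly below the 2nd-percentile
value are masked first (`low_coverage_filter = 0.02`): their bias is
undefined and their entries are excluded downstream. Because the cut is
strict, a perfectly uniform matrix masks nothing and is a fixed point of the
iteration.

One identifiability caveat matters later: balancing a matrix
$\mathrm{diag}(b)\,M\,\mathrm{diag}(b)$ returns $b$ times the balancing
factors of the structure matrix $M$ itself. For a finite chromosome with
power-law distance decay those structure factors are not flat — bins near
the chromosome ends genuinely see fewer close partners — so the ICE bias
estimates the true bias only up to a deterministic "edge factor". The loop
caller removes this factor explicitly (below). For the same reason, bias
*recovery* is only checkable on a matrix with product structure (no decay),
which is what the bias-recovery tests simulate.

## TAD calling

TADs are called on 40 kb normalized matrices with a diamond-statistic
procedure in the TopDom style, with window `w = 5` bins and boundary
p-cutoff 0.05 (the common defaults; the calling resolution follows standard
practice for domain-scale analysis).

1. The matrix is distance-normalized: each entry is divided by the
   chromosome's mean count at its bin distance (observed/expected). This
   step is essential: the raw cross-boundary entries lie at systematically
   larger genomic distances than the within-domain entries they are
   compared with, so without it the boundary test conflates genomic
   separation with domain structure and, at high coverage, fires on every
   candidate.
2. The bin signal at the boundary between bins $i$ and $i{+}1$ is the mean
   of the $w \times w$ diamond spanning bins $(i-w+1..i)\times(i+1..i+w)$,
   truncated at chromosome ends.
3. Candidate boundaries are local minima of the bin signal relative to a
   least-squares linear trend fitted within $\pm w$ bins.
4. Each candidate is kept when a one-sided rank-sum test finds the
   cross-boundary diamond entries smaller than the pooled within-side
   upper-triangle entries (windows of $w$) at `p < 0.05`.
5. Domains are the intervals between consecutive retained boundaries
   (minimum two bins). Masked runs of three or more bins break domains;
   shorter masked runs are bridged, with the diamond means simply ignoring
   missing entries — isolated low-coverage bins should not fragment
   domains.

## Cross-line TAD classification

Two TADs from different lines match when both boundary shifts are at most
80 kb (two 40 kb bins) **or** they reciprocally overlap at least 80% of
*both* lengths. The reciprocal reading prevents a small TAD from matching a
huge one, which would contradict any size comparison between classes.
Matching within a line pair is one-to-one, resolved greedily by decreasing
reciprocal overlap with coordinate-order tie-breaking, so results are
deterministic. A TAD entity is *common* when the three pairwise matches
close a triangle, *normal-specific* when a normal TAD matches neither
cancer line, and *cancer-specific* when the two cancer lines match each
other and neither member matches the normal line. Size comparisons between
classes use two-sided rank-sum tests with Benjamini-Hochberg (BH)
adjustment; entity size is the mean of member sizes.

A normal TAD is reported as *split* when at least two cancer TADs each lie
inside it with at least 80% of their own length and jointly cover at least
80% of it. This is a geometric rule; a per-TAD statistical test cannot be
reconstructed from a genome-wide rank-sum, so the global size test is
reported separately.

## TAD chromatin states

A TAD is *enriched* for a histone mark when it (a) intersects at least one
top-ranked peak of that mark and (b) has a per-TAD mean signal at or above
the 75th percentile of per-TAD means for that mark. The top-ranked set is
the strongest `min(30000, ceiling(0.25 * n))` peaks by score, which honours
both the absolute cap and the top-quartile reading when peak totals differ.
Per-TAD signal means are length-weighted over the binned signal track.
When several marks are enriched the state label follows the precedence
H3K36me3 > H3K27me3 > H3K9me3 — the active mark wins — and the raw flags are
kept alongside so no information is lost; TADs enriched for nothing are
labelled `other`. Note the structural assumption: the quantile rule can
label at most ~25% of TADs per mark, so it presumes no mark dominates the
genome.

State changes are assessed on common TADs by annotating the *same* interval
set in both conditions and flagging label differences; per initial-state
group the fraction changed is reported and groups are compared with
two-sided Fisher exact tests, BH-adjusted. The random-TAD empirical null
re-runs the enrichment call on 100 seeded sets of non-overlapping random
intervals with sizes uniform in 280-440 kb; empirical p-values use the
add-one rule $(1 + \#\{\text{null} \ge \text{obs}\})/(n+1)$, which cannot
return zero and reproduces the `p = 1/101 < 0.01` convention at $n = 100$.

One caveat about interpreting that null on the synthetic data: the
generator paints histone signal uniformly across each planted domain, so a
random interval that lands inside an active domain is just as "enriched" as
the domain itself, and the per-set quantile threshold adapts to each random
set. Real TADs therefore hold no advantage over size-matched random
intervals in this world and the empirical p is expected to be
non-significant; on real chromatin, where signal respects domain
boundaries, the same statistic discriminates. The machinery and the add-one
convention are validated separately on constructed cases.

## Loop significance

Loops are called on 10 kb normalized matrices over the 50 kb-10 Mb distance
range. The null follows the distance-stratified binomial construction:
exact bin-distance strata up to 200 bins and log-spaced strata beyond, with
stratum contact probability $\hat p_d = \sum \text{counts}_d / (N \cdot
M_d)$, where $M_d$ counts **all** locus pairs at that distance including
zero-count pairs — the correct null for sparse matrices — and the profile is
smoothed with weighted non-increasing isotonic regression (pool-adjacent-
violators with the pair counts as weights, which preserves
$\sum_d \hat p_d M_d = 1$ and fills empty strata from their neighbours).
A dedicated weighted implementation is used because the smoothing must be
weighted by $M_d$ to keep that identity.

The per-pair test is bias-aware: the raw count $k_{ij}$ (normalized count
times bias product) is tested against
$X \sim \mathrm{Binomial}(N,\ \hat p_d\, b^*_i\, b^*_j)$. The corrected
bias $b^*$ is the ICE bias divided by the structure-only balancing factors
obtained by balancing the expected distance-profile matrix
$M_{ij} = \bar m_{|i-j|}$; by the equivariance noted above this removes the
deterministic edge factor exactly, and stratum probabilities are
re-estimated with $b^*$ before testing. Without this correction the null
systematically under-predicts short-range counts near chromosome ends and
produces spurious calls there.

The reported p-value is the mid-p tail $P(X > k) + \tfrac12 P(X = k)$. The
plain tail $P(X \ge k)$ of a discrete statistic has null expectation above
one half and is visibly super-uniform at moderate expected counts; the
mid-p distribution is calibrated to uniform (the null simulations in the
test suite verify a Kolmogorov-Smirnov distance below 0.05 over more than
$10^5$ pairs), while in the far tail that decides significance the two
definitions agree to within a factor of two. BH adjustment runs over all
in-range pairs — zero-count pairs included — and loops are the pairs with
`q < 0.05`.

## Regulatory elements and anchor annotation

Element sets are built sequentially per cell line: *promoters* are ±2 kb
windows around the TSS of expressed genes (mean $\log_2(\mathrm{RPKM}+1) >
1.5$ over replicates, strict); *enhancers* are the top 25k H3K27ac peaks by
score lying more than 2 kb from **any** annotated TSS (expressed or not);
*insulators* are the top 50k CTCF peaks overlapping neither promoters nor
enhancers. Each 10 kb loop anchor is labelled `P` if it overlaps any
promoter (≥ 1 bp), else `E`, else `I`, else `O`; the loop category is the
unordered label pair, and categories are ranked by frequency with
lexicographic tie-breaking.

Loop-fate fractions partition each element class into
looped-to-enhancer / insulator / own-class / unmarked / not-looped. An
element in several loops is assigned by partner priority — the opposite
regulatory partner first (promoters: E > I > P > O; enhancers: P > I > E >
O; insulators: P > E > I > O) — so the fractions are disjoint and sum to 1.
The shuffled-anchor null places the observed number of non-overlapping
10 kb anchors uniformly on one chromosome 100 times and compares the number
of distinct elements overlapped, again with the add-one rule.

## Cross-line E-P loops, differential tests, expression

Enhancer-promoter (category `PE`) loops are matched across lines by exact
anchor-bin equality — no tolerance, deterministic and conservative — and
classified common / normal-specific / cancer-specific by the same three-set
logic as TADs; a loop found in the normal line and exactly one cancer line
carries no label. Differential contact frequency uses, per loop and per
cancer line, the 2×2 table of raw loop count versus the line's total
in-range contact sum, a two-sided Fisher exact test, and BH across loops;
with two cancer lines a loop is called differential when both
cancer-vs-normal tests pass with concordant direction.

Expression: RPKM, strict expressed calls as above, fold change
$(\bar x_{\text{cancer}}+1)/(\bar x_{\text{normal}}+1)$ on condition means
(the pseudocount keeps fold changes finite for genes silent in normal
cells), a two-sided t test on $\log_2(\mathrm{RPKM}+1)$ with BH as the
differential test, and two-sided rank-sum comparisons of fold-change
distributions between gene sets (genes whose promoters anchor
cancer-specific, normal-specific or common E-P loops, versus background).
Rank-sum tests switch to full permutation enumeration on midranks when both
groups have at most eight observations, which handles ties exactly.

## The synthetic-data generator

`simulate_dataset()` plants every structure the pipeline is meant to
detect, with the ground truth recorded so recovery is measurable. Per
chromosome (default two chromosomes of 20 Mb at 10/40 kb resolutions):

* A normal TAD partition of 25 domains (minimum 8 coarse bins); the five
  largest domains split into two cancer domains each, shared by both cancer
  lines. Expected counts follow $C\,(d+1)^{-\alpha}$ with $\alpha = 1$,
  multiplied by `tad_boost = 3` inside a domain and `loop_boost = 5` at
  exactly the planted anchor pairs (a point enrichment keeps recovery
  criteria unambiguous); counts are Poisson with per-bin log-normal bias
  (log-sd 0.3), and $C$ is set so the expected mass per chromosome matches
  `depth = 4e7` — deep enough that 10 kb pairs inside the 50 kb-10 Mb
  calling range are rarely empty, emulating deeply sequenced pooled
  libraries. `depth_for_diagonal()` converts a target mean diagonal count
  at a chosen resolution into a depth, for shallower regimes.
* Twelve loops per specificity class per chromosome (common /
  normal-specific / cancer-specific), each an enhancer-promoter pair at
  distances 60 kb-2 Mb, anchors kept clear of TAD boundaries and of each
  other.
* TAD states drawn with prevalences 0.15 / 0.15 / 0.12 / 0.58 for
  H3K36me3 / H3K27me3 / H3K9me3 / other — each mark deliberately below the
  25% cap of the quantile enrichment rule, with margin for sampling noise —
  and four common TADs per chromosome flip state between normal and cancer,
  with flip targets cycled so no mark crosses the cap. Peaks (one per
  ~15 kb of domain, at least 12) and a high/low binned signal track are
  generated per mark from the condition's state assignment.
* H3K27ac peaks in active domains plus a strong peak at every planted
  enhancer anchor present in the condition; background H3K27ac peaks are
  excluded from all planted anchor bins so anchor acetylation is exactly
  condition-specific. CTCF at domain boundaries and loop anchors plus
  background; an NDR nested at the centre of every H3K27ac peak; a TF that
  in cancer conditions binds 30% of all active-enhancer peaks (NDR-sized,
  at peak centres).
* 400 background genes per chromosome with density weighted by domain
  state (highest in active domains), one gene at every planted promoter
  anchor, and three RPKM replicates per condition with replicate noise
  sd 0.25 on the $\log_2$ scale; genes at cancer-specific promoter anchors
  gain a 4× expression effect in both cancer lines.

Everything derives from one root seed through named substreams, so a
dataset, and every pipeline output computed from it, is byte-reproducible.

What the generator does **not** emulate: A/B compartments, hierarchical or
nested domains, inter-chromosomal contacts, read-level artefacts
(duplicates, mappability structure), peak-calling noise, copy-number
aberrations, and anchor-width variability (planted loops sit at exactly one
bin pair). Passing recovery tests on these data therefore demonstrates the
correctness and calibration of the machinery under the stated generative
model, not performance on real libraries, where boundary sharpness, loop
anchor width and bias structure are all less tidy.

## Problem sizes and degenerate inputs

The shipped tests and the acceptance script run desk-scale problems chosen
to exercise every code path: full three-line pipelines on 2×20 Mb genomes,
null calibrations on single 20 Mb or 8 Mb chromosomes, and 100-replicate
Monte-Carlo checks on 2 Mb chromosomes. Degenerate inputs are handled
explicitly: chromosomes shorter than $2w$ bins yield no TADs with a
warning; empty peak sets disable the affected enrichment; groups or sets
with fewer than two members skip their comparison with a notice; an empty
triplet file is a valid all-zero matrix; non-convergent ICE warns and
returns the achieved deviation.

## Known limitations

* The binomial null assumes independent pairs; within-domain enrichment is
  genuine signal under this model, so on matrices with domain structure
  many called "loops" are domain-interior contacts. Interpretation of loop
  lists should always be together with the anchor categories.
* The state classifier's quantile rule cannot label more than a quarter of
  TADs per mark and has no notion of mixed states within one TAD.
* Cross-line loop matching at exact 10 kb anchor equality is conservative;
  a one-bin tolerance would trade specificity for sensitivity.
* The differential-expression test is a t test on log-transformed RPKM —
  appropriate for three clean replicates of simulated data; count-based
  models (e.g. negative-binomial GLMs) are preferable for real libraries.
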