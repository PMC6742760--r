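# hicstates

Comparative 3D-epigenome analysis of binned Hi-C contact maps across cell
lines, for studies that ask how chromatin architecture differs between a
normal and one or more derived (e.g. cancer) cell lines: which
topologically associating domains (TADs) appear, disappear or split; how
their histone-mark states change; which chromatin loops are
condition-specific; which enhancer–promoter (E-P) loops gain activity; and
what happens to the expression of the genes at their anchors. It is aimed
at computational genomicists who have HiC-Pro-style binned matrices,
ChIP-seq peak BEDs, NDR intervals and an expression table per cell line,
and want a reproducible, statistically calibrated pipeline from matrices to
annotated loop and domain tables.

## What it computes

* **ICE balancing** — iterative correction of per-bin multiplicative bias,
  `b_i ← b_i · m_i / m̄` to equal marginals, with low-coverage masking.
* **TAD calling** at 40 kb — diamond (binSignal) statistic on
  observed/expected counts, local-minimum boundary candidates against a
  local linear trend, one-sided rank-sum boundary test.
* **Cross-line TAD classification** — two TADs match when both boundary
  shifts are ≤ 80 kb or reciprocal overlap ≥ 80% of both; common /
  normal-specific / cancer-specific classes by three-set logic, rank-sum
  size comparisons (BH-adjusted), and geometric split-TAD detection.
* **TAD chromatin states** — a TAD is enriched for a mark when it holds a
  top-ranked peak *and* its mean signal reaches the top quartile across
  TADs; states labelled with active-mark precedence; state-change detection
  on common TADs with Fisher tests; a 100-set random-TAD empirical null.
* **Loop calling** at 10 kb — distance-stratified binomial test
  `X ~ Binom(N, p_d·b_i·b_j)` against an isotonically smoothed decay
  profile (zero-count pairs included in the multiple-testing family;
  edge-corrected bias; mid-p tail), BH control at q < 0.05 over 50 kb–10 Mb.
* **Regulatory anchors** — sequential promoter (TSS ± 2 kb of expressed
  genes) > enhancer (top H3K27ac peaks > 2 kb from any TSS) > insulator
  (top CTCF peaks overlapping neither) labelling, category rankings,
  loop-fate fractions, shuffled-anchor empirical nulls.
* **E-P loop specificity** — exact anchor matching across lines; common /
  normal-specific / cancer-specific sets; per-loop Fisher differential
  contact tests against both cancer lines; TF-bound looped-enhancer
  fractions with NDR restriction and target-gene lists.
* **Expression consequences** — RPKM, expressed-gene calls
  (mean log2(RPKM+1) > 1.5), differential expression (FC > 2, adj p < 0.05),
  and rank-sum comparisons of fold changes between anchor gene sets.
* **A synthetic-data generator** (`simulate_dataset()`) that plants TADs,
  splits, state flips, loops of all three specificity classes, peaks, NDRs,
  TF binding, bias and expression effects with recorded ground truth, so
  the whole pipeline is verifiable end to end.

## Worked example

Simulate a one-chromosome three-line dataset with known ground truth and
run the full pipeline:

```r
library(hicstates)

cfg <- sim_config(n_chroms = 1, chrom_length = 8e6, depth = 1e7,
                  n_tads_per_chrom = 10, n_split_tads = 2,
                  n_loops_per_class = 5, seed = 42)
ds  <- simulate_dataset(cfg)
res <- run_pipeline(ds, outdir = "example_run", seed = 42)

res$classification
#> tad_classification:
#>          common normal_specific cancer_specific
#>               8               2               4

head(res$tads$normal, 3)
#>   chrom  start     end    size
#> 1  chr1      0  440000  440000
#> 2  chr1 440000  840000  400000
#> 3  chr1 840000 2080000 1240000

table(res$ep_loops$specificity)
#> cancer_specific          common normal_specific       unlabeled
#>              94              29              65             266

res$recovery[, c("tad_boundary_recovery", "loop_sensitivity_normal",
                 "ep_cancer_specific_sensitivity", "ep_normal_mislabels")]
#>   tad_boundary_recovery loop_sensitivity_normal ep_cancer_specific_sensitivity
#> 1                     1                       1                            0.8
#>   ep_normal_mislabels
#> 1                   0

round(res$tf_bound$fraction, 3)
#> [1] 0.371
```

Reading the output: all planted TAD boundaries were recovered and the two
split domains produce the 2 normal-specific / 4 cancer-specific entities;
the E-P table contains the planted loops (4 of the 5 planted
cancer-specific loops recovered here, none mislabelled as normal-specific)
plus domain-driven contacts whose anchors happen to carry regulatory
elements; and 37% of cancer-specific looped enhancers are bound by the
simulated TF, close to the 30% binding rate the generator plants.
`example_run/` holds the full tabular outputs (TAD BEDs, loop BEDPEs,
classification, state-change, differential and gene-set tables, and a JSON
run manifest).

On real data, build the same `dataset` structure from files using
`read_contact_matrix()`, `read_bed()` and `read_gene_table()`, or call the
stage functions (`ice_normalize`, `coarsen`, `call_tads`, `match_tads`,
`classify_tad_states`, `estimate_decay`, `call_significant_loops`,
`build_regulatory_sets`, `annotate_anchors`, `classify_ep_loops`, ...)
directly.

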