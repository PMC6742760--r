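# Loop significance, regulatory sets, anchor annotation, fates, nulls,
# specificity classification, differential tests, TF intersection.

test_that("pairs at their stratum expectation are never significant", {
  # flat normalized matrix: every in-range pair equals its stratum mean
  m <- constant_matrix(n_bins = 60, value = 20, resolution = 1e4)
  m$normalized <- TRUE
  dec <- estimate_decay(m, range = c(5e4, 6e5))
  lp <- call_significant_loops(m, dec, range = c(5e4, 6e5),
                               return_pvalues = TRUE)
  expect_equal(nrow(lp), 0)
  pv <- attr(lp, "pvalues")
  expect_true(all(abs(pv - 0.5) < 0.2))   # mid-p of k = E[k] sits near 1/2
})

test_that("loop p-values equal the hand-computed mid-p binomial tail", {
  # one inflated pair on an otherwise flat matrix, no bias/mask
  n <- 60
  bins <- make_bin_table(c(chr1 = n * 1e4), 1e4)
  pr <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  x <- rep(20, nrow(pr))
  hot <- which(pr[, 1] == 10 & pr[, 2] == 20)   # distance 10 bins
  x[hot] <- 60
  m <- hic_matrix(bins, pr[, 1], pr[, 2], x, 1e4, normalized = TRUE)
  dec <- estimate_decay(m, range = c(5e4, 6e5))
  lp <- call_significant_loops(m, dec, range = c(5e4, 6e5))
  expect_equal(nrow(lp), 1)
  expect_equal(lp$bin1, 10); expect_equal(lp$bin2, 20)
  # reconstruct the null exactly: stratum lambda at d=10 (after isotonic fit
  # over identical strata) with the edge factor of a flat profile (none)
  N <- round(dec$N_total)
  lam <- (20 * (n - 10 - 1) + 60) / (n - 10)
  p_manual <- pbinom(60, N, lam / N, lower.tail = FALSE) +
    0.5 * dbinom(60, N, lam / N)
  expect_equal(lp$p, p_manual, tolerance = 1e-6)
})

test_that("regulatory sets are built sequentially with the stated thresholds", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
                      tss = c(50000, 200000), length = 1000,
                      r1 = c(2.2, 0), r2 = c(2.2, 0), r3 = c(2.1, 0))
  # g1 mean log2(RPKM+1) = 1.68 > 1.5 -> expressed; g2 not
  expressed <- call_expressed(as.matrix(genes[, c("r1", "r2", "r3")]))
  expect_equal(expressed, c(TRUE, FALSE))
  k27 <- data.frame(chrom = "chr1",
                    start = c(51000, 201500, 300000),
                    end = c(53000, 203500, 302000), score = c(5, 4, 3))
  ctcf <- data.frame(chrom = "chr1", start = c(49000, 400000),
                     end = c(50500, 400400), score = c(9, 8))
  rs <- build_regulatory_sets(genes, expressed, k27, ctcf)
  # one promoter: g1 TSS +/- 2 kb
  expect_equal(nrow(rs$promoters), 1)
  expect_equal(rs$promoters$start, 48000)
  # peak 1 kb from the g1 TSS excluded; peak 1.5 kb from the g2 TSS excluded
  # too (unexpressed genes still count for the TSS-distance rule)
  expect_equal(rs$enhancers$start, 300000)
  # CTCF overlapping the promoter window dropped
  expect_equal(rs$insulators$start, 400000)
})

test_that("anchors are labelled sequentially and categories ranked", {
  rs <- structure(list(
    promoters = data.frame(chrom = "chr1", start = 1e5, end = 1.1e5),
    enhancers = data.frame(chrom = "chr1", start = c(1.05e5, 5e5),
                           end = c(1.15e5, 5.1e5)),
    insulators = data.frame(chrom = "chr1", start = 9e5, end = 9.1e5)),
    class = "reg_set")
  lp <- toy_loops("chr1", c(1e5, 4.95e5, 2e6), c(5e5, 9e5, 3e6))
  ann <- annotate_anchors(lp, rs)
  # anchor overlapping both promoter and enhancer -> P
  expect_equal(ann$anchor1_label, c("P", "E", "O"))
  expect_equal(ann$anchor2_label, c("E", "I", "O"))
  expect_equal(ann$category, c("PE", "EI", "OO"))
})

test_that("category ranking sorts by count with lexicographic ties", {
  res <- 1e4
  # elements tiled so that anchors at chosen bins are pure E or pure P
  e_bins <- seq(10, 40, by = 2) * res
  p_bins <- seq(60, 90, by = 2) * res
  rs <- structure(list(
    promoters = data.frame(chrom = "chr1", start = p_bins, end = p_bins + 1e3),
    enhancers = data.frame(chrom = "chr1", start = e_bins, end = e_bins + 1e3),
    insulators = data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0))),
    class = "reg_set")
  # 5 E-E loops, 3 P-P loops, 2 P-E loops
  s1 <- c(e_bins[1:5], p_bins[1:3], p_bins[4:5])
  s2 <- c(e_bins[6:10], p_bins[6:8], e_bins[11:12])
  ann <- annotate_anchors(toy_loops("chr1", pmin(s1, s2), pmax(s1, s2)), rs)
  rank_tab <- attr(ann, "ranking")
  expect_equal(rank_tab$category, c("EE", "PP", "PE"))
  expect_equal(rank_tab$count, c(5L, 3L, 2L))
  expect_equal(top_categories(ann, 2)$category, c("EE", "PP"))
})

test_that("loop-fate fractions partition each element class", {
  rs <- structure(list(
    promoters = data.frame(chrom = "chr1", start = c(1e5, 7e5), end = c(1.1e5, 7.1e5)),
    enhancers = data.frame(chrom = "chr1", start = 5e5, end = 5.1e5),
    insulators = data.frame(chrom = "chr1", start = 9e5, end = 9.1e5)),
    class = "reg_set")
  # promoter 1 loops to the enhancer AND the insulator; promoter 2 unlooped
  lp <- toy_loops("chr1", c(1e5, 1e5), c(5e5, 9e5))
  ann <- annotate_anchors(lp, rs)
  ff <- loop_fate_fractions(rs, ann)
  prom <- ff[ff$class == "promoters", ]
  expect_equal(prom$fraction[prom$fate == "loops_to_E"], 0.5)   # priority E > I
  expect_equal(prom$fraction[prom$fate == "loops_to_I"], 0)
  expect_equal(prom$fraction[prom$fate == "not_looped"], 0.5)
  for (cl in unique(ff$class)) {
    expect_equal(sum(ff$fraction[ff$class == cl]), 1, tolerance = 1e-9)
  }
})

test_that("shuffled-anchor null follows the add-one convention and saturates", {
  # three elements exactly at the three real anchors of a large chromosome:
  # the real anchors hit all three, random anchors essentially never do
  lp <- toy_loops("chr1", c(1e6, 4e6, 7e6), c(2e6, 5e6, 8e6))
  anchors <- data.frame(chrom = "chr1",
                        start = c(lp$start1, lp$start2), end = c(lp$end1, lp$end2))
  rs <- structure(list(promoters = anchors[1:2, ], enhancers = anchors[3:4, ],
                       insulators = anchors[5:6, ]), class = "reg_set")
  nl <- shuffle_anchor_null(lp, rs, chrom = "chr1", chrom_length = 1e8,
                            n = 100, seed = 5)
  expect_equal(nl$p, rep(1 / 101, 3))
  expect_true(all(nl$p < 0.01))
  # element covering the whole chromosome: every shuffle hits it
  rs2 <- structure(list(promoters = data.frame(chrom = "chr1", start = 0, end = 1e8),
                        enhancers = anchors[0, ], insulators = anchors[0, ]),
                   class = "reg_set")
  nl2 <- shuffle_anchor_null(lp, rs2, chrom = "chr1", chrom_length = 1e8,
                             n = 50, seed = 5)
  expect_equal(nl2$p[1], 1)
  # determinism under the seed
  nl3 <- shuffle_anchor_null(lp, rs, chrom = "chr1", chrom_length = 1e8,
                             n = 100, seed = 5)
  expect_identical(nl, nl3)
})

test_that("E-P loop specificity follows the three-set logic", {
  mk <- function(start1s, start2s) {
    lp <- toy_loops("chr1", start1s, start2s)
    lp$category <- "PE"
    lp
  }
  # loop A in all; loop B in both cancers; loop C in normal only;
  # loop D in normal + one cancer (stays unlabeled)
  A <- c(1e6, 2e6); B <- c(3e6, 4e6); C <- c(5e6, 6e6); D <- c(7e6, 8e6)
  normal <- mk(c(A[1], C[1], D[1]), c(A[2], C[2], D[2]))
  c1 <- mk(c(A[1], B[1], D[1]), c(A[2], B[2], D[2]))
  c2 <- mk(c(A[1], B[1]), c(A[2], B[2]))
  ep <- classify_ep_loops(list(normal = normal, c1 = c1, c2 = c2))
  lab <- setNames(ep$specificity, ep$key)
  expect_equal(unname(lab["chr1:1000000-2000000"]), "common")
  expect_equal(unname(lab["chr1:3000000-4000000"]), "cancer_specific")
  expect_equal(unname(lab["chr1:5000000-6000000"]), "normal_specific")
  expect_equal(unname(lab["chr1:7000000-8000000"]), "unlabeled")
  # partition: one label per loop
  expect_equal(anyDuplicated(ep$key), 0)
})

test_that("differential loop test matches hypergeometric enumeration", {
  d <- differential_loop_test(10, 1000, 1, 1000)
  expect_equal(d$p, oracle_fisher(10, 990, 1, 999), tolerance = 1e-12)
  expect_lt(d$p, 0.05)
  # identical proportions and empty tables give p = 1
  expect_equal(differential_loop_test(5, 1000, 5, 1000)$p, 1)
  expect_equal(differential_loop_test(0, 100, 0, 100)$p, 1)
  expect_error(differential_loop_test(1, 0, 1, 10), "positive")
})

test_that("TF-bound looped-enhancer fraction counts distinct enhancers", {
  # 10 enhancers each looping to one promoter; TF covers 3 of them
  starts <- (1:10) * 1e6
  rs <- structure(list(
    promoters = data.frame(chrom = "chr1", start = starts + 5e5,
                           end = starts + 5.1e5),
    enhancers = data.frame(chrom = "chr1", start = starts, end = starts + 2e3),
    insulators = data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0))),
    class = "reg_set")
  lp <- toy_loops("chr1", starts, starts + 5e5)
  ann <- annotate_anchors(lp, rs)
  expect_true(all(ann$category == "PE"))
  tf <- data.frame(chrom = "chr1", start = starts[c(2, 5, 9)] + 100,
                   end = starts[c(2, 5, 9)] + 400)
  genes <- data.frame(gene_id = sprintf("g%d", 1:10), chrom = "chr1",
                      strand = "+", tss = starts + 5.05e5, length = 1000)
  out <- tf_bound_looped_enhancers(ann, rs, tf, genes = genes)
  expect_equal(out$fraction, 0.3)
  expect_equal(out$target_genes, c("g2", "g5", "g9"))
  # no TF peaks -> 0; one giant peak -> 1
  expect_equal(tf_bound_looped_enhancers(ann, rs, tf[0, ])$fraction, 0)
  giant <- data.frame(chrom = "chr1", start = 0, end = 2e7)
  expect_equal(tf_bound_looped_enhancers(ann, rs, giant)$fraction, 1)
})
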