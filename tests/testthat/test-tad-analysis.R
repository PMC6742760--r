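# TAD calling, cross-line matching, size tests, split detection.

test_that("uniform matrix yields no boundaries and one domain", {
  m <- constant_matrix(n_bins = 40, value = 8)
  m$normalized <- TRUE
  tads <- call_tads(m)
  expect_equal(nrow(tads), 1)
  expect_equal(tads$start, 0)
  expect_equal(tads$end, 40 * 4e4)
  expect_equal(nrow(attr(tads, "boundaries")), 0)
})

test_that("two-block diagonal matrix yields exactly one boundary at the junction", {
  n <- 40
  bins <- make_bin_table(c(chr1 = n * 4e4), 4e4)
  pr <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  blk <- function(i) ifelse(i <= 20, 1L, 2L)
  x <- ifelse(blk(pr[, 1]) == blk(pr[, 2]), 10, 0)
  keep <- x > 0
  m <- hic_matrix(bins, pr[keep, 1], pr[keep, 2], x[keep], 4e4, normalized = TRUE)
  tads <- call_tads(m)
  b <- attr(tads, "boundaries")
  expect_equal(nrow(b), 1)
  expect_equal(b$pos, 20 * 4e4)
  expect_equal(nrow(tads), 2)
})

test_that("planted TAD boundaries are recovered on a simulated chromosome", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 8e6, depth = 8e6, seed = 13,
                    n_tads_per_chrom = 10, n_split_tads = 2,
                    n_loops_per_class = 4)
  tr <- make_ground_truth(cfg)
  m <- simulate_contact_matrix(cfg, tr, "normal")
  ice <- ice_normalize(coarsen(m, 4))
  tads <- call_tads(ice$matrix)
  planted <- sort(unique(c(tr$tads_normal$start, tr$tads_normal$end)))
  planted <- planted[planted > 0 & planted < cfg$chrom_length]
  called <- sort(unique(c(tads$start, tads$end)))
  called <- called[called > 0 & called < cfg$chrom_length]
  recovery <- mean(sapply(planted, function(p) any(abs(called - p) <= 4e4)))
  expect_gte(recovery, 0.9)
})

test_that("pairwise TAD matching follows the boundary/overlap rule", {
  a <- data.frame(chrom = "chr1", start = 1e6, end = 1.4e6)
  b <- data.frame(chrom = "chr1", start = 1.04e6, end = 1.44e6)
  expect_equal(nrow(hicstates:::.match_tad_pair(a, b)), 1)  # 40 kb shifts
  # 190 kb end shift but 81% reciprocal overlap still matches
  a <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  b <- data.frame(chrom = "chr1", start = 0, end = 8.1e5)
  expect_equal(nrow(hicstates:::.match_tad_pair(a, b)), 1)
  # 79% reciprocal overlap and large shifts: no match
  b <- data.frame(chrom = "chr1", start = 0, end = 7.9e5)
  expect_equal(nrow(hicstates:::.match_tad_pair(a, b)), 0)
})

test_that("identical TAD lists in three lines are all common", {
  tads <- random_tad_list(n_max = 5)
  cls <- match_tads(list(normal = tads, c1 = tads, c2 = tads))
  expect_equal(unname(cls$counts["common"]), nrow(tads))
  expect_true(all(cls$labels$normal == "common"))
  expect_equal(sum(cls$chains$class != "common"), 0)
})

test_that("overlapping TADs within one line are rejected", {
  bad <- data.frame(chrom = "chr1", start = c(0, 1e5), end = c(2e5, 3e5))
  ok <- data.frame(chrom = "chr1", start = 0, end = 2e5)
  expect_error(match_tads(list(a = bad, b = ok, c = ok)), "overlapping")
})

test_that("three-set classification matches a brute-force oracle", {
  set.seed(21)
  for (k in 1:60) {
    tn <- random_tad_list(); t1 <- random_tad_list(); t2 <- random_tad_list()
    cls <- match_tads(list(n = tn, c1 = t1, c2 = t2))
    m_n1 <- oracle_match_pair(tn, t1); m_n2 <- oracle_match_pair(tn, t2)
    m_12 <- oracle_match_pair(t1, t2)
    # common: triangle closes
    common <- 0
    for (a in seq_len(nrow(tn))) {
      b <- m_n1$b[match(a, m_n1$a)]; c2 <- m_n2$b[match(a, m_n2$a)]
      if (!is.na(b) && !is.na(c2)) {
        bb <- m_12$b[match(b, m_12$a)]
        if (!is.na(bb) && bb == c2) common <- common + 1
      }
    }
    normal_spec <- sum(!(seq_len(nrow(tn)) %in% m_n1$a) &
                         !(seq_len(nrow(tn)) %in% m_n2$a))
    cancer_spec <- 0
    for (b in seq_len(nrow(t1))) {
      c2 <- m_12$b[match(b, m_12$a)]
      if (!is.na(c2) && !(b %in% m_n1$b) && !(c2 %in% m_n2$b)) {
        cancer_spec <- cancer_spec + 1
      }
    }
    expect_equal(unname(cls$counts["common"]), common)
    expect_equal(unname(cls$counts["normal_specific"]), normal_spec)
    expect_equal(unname(cls$counts["cancer_specific"]), cancer_spec)
  }
})

test_that("TAD size comparison flags the planted ordering with exact p", {
  chains <- data.frame(class = rep(c("normal_specific", "cancer_specific"),
                                   each = 4),
                       size = c(rep(200, 4), rep(100, 4)))
  cls <- structure(list(chains = chains), class = "tad_classification")
  rep_out <- compare_tad_sizes(cls)
  expect_equal(rep_out$p, 2 / 70, tolerance = 1e-12)
  # identical size multisets: no difference
  chains$size <- rep(100, 8)
  cls$chains <- chains
  expect_gt(compare_tad_sizes(cls)$adj_p, 0.05)
})

test_that("split-TAD detection follows the containment/coverage rule", {
  n <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  kids <- data.frame(chrom = "chr1", start = c(0, 4e5), end = c(4e5, 1e6))
  sp <- detect_split_tads(n, kids)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$n_children, 2)
  # identical partitions: one child covers the parent but >= 2 are required
  expect_equal(nrow(detect_split_tads(n, n)), 0)
  # child half outside the parent does not count
  kids2 <- data.frame(chrom = "chr1", start = c(0, 8e5), end = c(4e5, 1.6e6))
  expect_equal(nrow(detect_split_tads(n, kids2)), 0)
})
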