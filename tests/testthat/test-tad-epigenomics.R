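# TAD state annotation, gene density, random-TAD null, state changes.

test_that("per-TAD signal mean is length-weighted", {
  track <- data.frame(chrom = "chr1", start = c(0, 50), end = c(50, 100),
                      value = c(1, 3))
  tads <- data.frame(chrom = "chr1", start = c(0, 0), end = c(100, 75))
  m <- mean_signal_per_tad(tads, track)
  expect_equal(as.numeric(m), c(2, (50 * 1 + 25 * 3) / 75), tolerance = 1e-12)
  # constant track gives the constant everywhere
  track2 <- data.frame(chrom = "chr1", start = 0, end = 100, value = 2)
  expect_equal(as.numeric(mean_signal_per_tad(tads, track2)), c(2, 2))
  # TAD with no coverage is flagged and 0
  tads3 <- data.frame(chrom = "chr2", start = 0, end = 100)
  m3 <- mean_signal_per_tad(tads3, track)
  expect_equal(as.numeric(m3), 0)
  expect_true(attr(m3, "uncovered"))
})

test_that("state enrichment needs both a top peak and a top-quartile signal", {
  # 10 TADs; 12 peaks of which the top quarter (3) lie in TADs 1-3; signal
  # high in TADs 1-3 and 8
  tads <- data.frame(chrom = "chr1", start = (0:9) * 1e5, end = (1:10) * 1e5)
  peaks <- data.frame(chrom = "chr1",
                      start = c(1e4, 1.2e5, 2.3e5, 3.1e5 + (0:8) * 1e3),
                      end = c(1.2e4, 1.25e5, 2.35e5, 3.12e5 + (0:8) * 1e3),
                      score = c(9, 8, 7, 2 - (0:8) / 10))
  track <- data.frame(chrom = "chr1", start = (0:9) * 1e5, end = (1:10) * 1e5,
                      value = c(5, 5, 5, 1, 1, 1, 1, 5, 1, 1))
  ann <- suppressWarnings(classify_tad_states(
    tads, list(H3K36me3 = peaks), list(H3K36me3 = track)))
  expect_equal(ann$state[1:3], rep("H3K36me3", 3))
  expect_equal(ann$state[8], "other")      # signal but no peak
  expect_equal(ann$state[4], "other")      # neither
  # no peaks at all: nothing enriched regardless of signal
  ann0 <- suppressWarnings(classify_tad_states(
    tads, list(H3K36me3 = peaks[0, ]), list(H3K36me3 = track)))
  expect_true(all(ann0$state == "other"))
})

test_that("state label follows the active-mark precedence", {
  tads <- data.frame(chrom = "chr1", start = 0, end = 1e5)
  pk <- data.frame(chrom = "chr1", start = 10, end = 100, score = 5)
  tr <- data.frame(chrom = "chr1", start = 0, end = 1e5, value = 3)
  ann <- suppressWarnings(classify_tad_states(
    tads, list(H3K9me3 = pk, H3K36me3 = pk, H3K27me3 = pk),
    list(H3K9me3 = tr, H3K36me3 = tr, H3K27me3 = tr)))
  expect_equal(ann$state, "H3K36me3")
  expect_true(ann$H3K9me3_enriched)        # raw flags preserved
})

test_that("gene density classes use the 0 / 1-5 / >5 boundaries", {
  tads <- data.frame(chrom = "chr1", start = c(0, 1e5, 2e5), end = c(1e5, 2e5, 3e5))
  genes <- data.frame(gene_id = sprintf("g%d", 1:11), chrom = "chr1",
                      tss = c(1.1e5 + (0:4) * 100, 2.1e5 + (0:5) * 100))
  cls <- gene_density_class(tads, genes)
  expect_equal(as.character(cls), c("desert", "poor", "enriched"))
  expect_equal(attr(cls, "n_genes"), c(0, 5, 6))
})

test_that("random-TAD null is seeded and follows the add-one convention", {
  sizes <- c(chr1 = 5e7, chr2 = 5e7)
  # enrichment function that gives 0 for any random set -> observed 5 beats all
  res <- random_tad_null(sizes, n_tads = 20, enrich_count = function(t) 0L,
                         observed = 5, n_sets = 100, seed = 4)
  expect_equal(res$p, 1 / 101)
  expect_lt(res$p, 0.01)
  # observed 0 can never beat a null count
  res0 <- random_tad_null(sizes, n_tads = 20, enrich_count = function(t) 0L,
                          observed = 0, n_sets = 100, seed = 4)
  expect_equal(res0$p, 1)
  # identical seeds give identical null draws
  f <- function(t) nrow(t[t$start < 1e7, ])
  r1 <- random_tad_null(sizes, 20, f, 3, n_sets = 20, seed = 9)
  r2 <- random_tad_null(sizes, 20, f, 3, n_sets = 20, seed = 9)
  expect_identical(r1$null_counts, r2$null_counts)
  # random sets respect the size range and do not overlap
  set.seed(1)
  tads <- hicstates:::random_intervals(sizes, 30, c(280000, 440000))
  expect_true(all(tads$size >= 280000 & tads$size <= 440000))
  for (ch in unique(tads$chrom)) {
    t <- tads[tads$chrom == ch, ]
    t <- t[order(t$start), ]
    if (nrow(t) > 1) expect_true(all(t$start[-1] >= t$end[-nrow(t)]))
  }
})

test_that("state-change detection: identical annotations change nothing", {
  ann <- data.frame(chrom = "chr1", start = c(0, 1e5), end = c(1e5, 2e5),
                    state = c("H3K36me3", "H3K9me3"))
  ch <- detect_state_changes(ann, ann)
  expect_true(all(!ch$tads$changed))
  expect_true(all(ch$fractions$fraction_changed == 0))
})

test_that("group comparison of change rates uses the exact Fisher test", {
  # [[8,2],[2,8]] toy: 10 TADs per group
  ann_n <- data.frame(chrom = "chr1", start = (0:19) * 1e5, end = (1:20) * 1e5,
                      state = rep(c("H3K9me3", "H3K36me3"), each = 10))
  ann_c <- ann_n
  ann_c$state[1:8] <- "other"     # 8/10 changed in group 1
  ann_c$state[11:12] <- "other"   # 2/10 changed in group 2
  ch <- detect_state_changes(ann_n, ann_c)
  expect_equal(ch$tests$p, oracle_fisher(8, 2, 2, 8), tolerance = 1e-12)
  expect_equal(ch$tests$p, 0.023, tolerance = 1e-3)
})

test_that("planted state flips in common TADs are detected from annotations", {
  cfg <- sim_config(n_chroms = 2, seed = 17)
  tr <- make_ground_truth(cfg)
  ann_n <- simulate_annotations(cfg, tr, "normal")
  ann_c <- simulate_annotations(cfg, tr, "cancerA")
  # common TADs = unsplit normal TADs, identical intervals in both partitions
  common <- tr$tads_normal[!tr$tads_normal$split, ]
  marks <- c("H3K36me3", "H3K27me3", "H3K9me3")
  st_n <- suppressWarnings(classify_tad_states(common, ann_n$peaks[marks],
                                               ann_n$tracks[marks]))
  st_c <- suppressWarnings(classify_tad_states(common, ann_c$peaks[marks],
                                               ann_c$tracks[marks]))
  ch <- detect_state_changes(st_n, st_c)
  flips <- tr$state_flips
  key <- paste0(common$chrom, ":", common$start)
  flagged <- ch$tads$changed[match(paste0(flips$chrom, ":", flips$start), key)]
  expect_gte(mean(flagged), 0.9)
  # direction recorded: recovered states match the planted flip labels mostly
  idx <- match(paste0(flips$chrom, ":", flips$start), key)
  expect_gte(mean(ch$tads$state_normal[idx] == flips$from), 0.85)
  expect_gte(mean(ch$tads$state_cancer[idx] == flips$to), 0.85)
})
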