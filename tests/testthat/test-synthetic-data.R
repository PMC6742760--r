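# Synthetic-data generator: determinism, decay model, planted structure,
# nesting and specificity constraints, expression effects.

small_cfg <- function(seed = 1, n_genes_per_chrom = 80, ...) {
  sim_config(n_chroms = 1, chrom_length = 4e6, depth = 2e6,
             n_tads_per_chrom = 5, n_split_tads = 1, n_loops_per_class = 3,
             n_genes_per_chrom = n_genes_per_chrom, seed = seed, ...)
}

test_that("the generator is deterministic under (seed, config)", {
  cfg <- small_cfg(seed = 31)
  t1 <- make_ground_truth(cfg); t2 <- make_ground_truth(cfg)
  expect_identical(t1$tads_normal, t2$tads_normal)
  expect_identical(t1$loops, t2$loops)
  m1 <- simulate_contact_matrix(cfg, t1, "cancerA")
  m2 <- simulate_contact_matrix(cfg, t2, "cancerA")
  expect_identical(m1$x, m2$x)
  a1 <- simulate_annotations(cfg, t1, "normal")
  a2 <- simulate_annotations(cfg, t2, "normal")
  expect_identical(a1$peaks$H3K27ac, a2$peaks$H3K27ac)
  expect_identical(a1$genes, a2$genes)
})

test_that("without structure the counts follow the power-law decay", {
  cfg <- small_cfg(seed = 5, tad_boost = 1, loop_boost = 1, bias_sd = 0)
  cfg$n_loops_per_class <- 0
  tr <- make_ground_truth(cfg)
  m <- simulate_contact_matrix(cfg, tr, "normal")
  D <- hicstates:::cm_dense(m, "chr1")
  n <- nrow(D)
  mean_at <- function(d) mean(D[cbind(1:(n - d), (1 + d):n)])
  # mean counts fall like (d+1)^-alpha: check the ratio at two distances
  expect_equal(mean_at(1) / mean_at(7), 8 / 2, tolerance = 0.1)
  expect_equal(mean_at(3) / mean_at(15), 16 / 4, tolerance = 0.1)
})

test_that("planted loop pairs exceed same-distance means in >= 95/100 replicates", {
  hits <- 0
  for (k in 1:100) {
    cfg <- sim_config(n_chroms = 1, chrom_length = 2e6, depth = 1e6,
                      n_tads_per_chrom = 3, n_split_tads = 0,
                      n_loops_per_class = 1, loop_boost = 5, seed = 1000 + k)
    tr <- make_ground_truth(cfg)
    lp <- tr$loops[tr$loops$class == "common", ][1, ]
    m <- simulate_contact_matrix(cfg, tr, "normal")
    D <- hicstates:::cm_dense(m, "chr1")
    n <- nrow(D); d <- lp$bin2 - lp$bin1
    others <- D[cbind(1:(n - d), (1 + d):n)][-lp$bin1]
    if (D[lp$bin1, lp$bin2] > mean(others)) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("annotation nesting and specificity constraints hold by construction", {
  cfg <- small_cfg(seed = 41)
  tr <- make_ground_truth(cfg)
  ann_n <- simulate_annotations(cfg, tr, "normal")
  ann_c <- simulate_annotations(cfg, tr, "cancerA")
  # every NDR nests inside some H3K27ac peak
  k27 <- ann_n$peaks$H3K27ac
  for (r in seq_len(nrow(ann_n$ndrs))) {
    nd <- ann_n$ndrs[r, ]
    expect_true(any(k27$chrom == nd$chrom & k27$start <= nd$start &
                      k27$end >= nd$end))
  }
  # normal condition lacks H3K27ac peaks at cancer-specific enhancer anchors
  cs <- tr$loops[tr$loops$class == "cancer_specific", ]
  enh_start <- ifelse(cs$promoter_anchor == 1, cs$start2, cs$start1)
  anchors <- data.frame(chrom = cs$chrom, start = enh_start,
                        end = enh_start + cfg$fine_resolution)
  ov_normal <- hicstates:::overlaps_any(anchors, ann_n$peaks$H3K27ac)
  ov_cancer <- hicstates:::overlaps_any(anchors, ann_c$peaks$H3K27ac)
  expect_false(any(ov_normal))
  expect_true(all(ov_cancer))
})

test_that("planted expression effects give median fold change above 2", {
  cfg <- sim_config(n_chroms = 2, chrom_length = 5e7, n_loops_per_class = 100,
                    n_genes_per_chrom = 600, expression_effect = 4, seed = 23)
  tr <- make_ground_truth(cfg)
  up <- tr$expression$upregulated
  expect_gte(length(up), 200)
  rpkm_mat <- tr$expression$rpkm
  idx <- match(up, rownames(rpkm_mat))
  fc <- (rowMeans(rpkm_mat[idx, paste0("cancerA_rep", 1:3)]) + 1) /
    (rowMeans(rpkm_mat[idx, paste0("normal_rep", 1:3)]) + 1)
  expect_gt(median(fc), 2)
})

test_that("gene density is highest in active TADs", {
  cfg <- small_cfg(seed = 19, n_genes_per_chrom = 300)
  tr <- make_ground_truth(cfg)
  tn <- tr$tads_normal
  cls <- gene_density_class(tn, tr$genes)
  dens <- attr(cls, "n_genes") / (tn$end - tn$start)
  active <- tn$state_normal == "H3K36me3"
  if (any(active) && any(!active)) {
    expect_gt(mean(dens[active]), mean(dens[!active]))
  }
})

test_that("a written dataset reads back with conserved content", {
  cfg <- small_cfg(seed = 3)
  ds <- simulate_dataset(cfg)
  out <- withr::local_tempdir()
  write_synthetic_dataset(ds, out)
  m <- read_contact_matrix(file.path(out, "normal_matrix.tsv"),
                           file.path(out, "normal_bins.bed"))
  expect_equal(hicstates:::cm_total(m), hicstates:::cm_total(ds$matrices$normal))
  g <- read_gene_table(file.path(out, "genes.tsv"))
  expect_equal(nrow(g), nrow(ds$genes))
  truth <- jsonlite::read_json(file.path(out, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$loops), nrow(ds$truth$loops))
})
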