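# Readers/writers: parsing, canonicalization, round trips.

test_that("read_bed parses 0-based half-open intervals and preserves order", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t0\t100\tp0\t2", "chr2\t500\t900\tpeak1\t7.5",
               "chr1\t50\t60\tp\t1"), f)
  bed <- read_bed(f)
  expect_equal(nrow(bed), 3)
  expect_equal(bed$chrom, c("chr1", "chr2", "chr1"))
  expect_equal(bed$start[1], 0)
  expect_equal(bed$end[2], 900)
  expect_equal(bed$score[2], 7.5)
})

test_that("read_bed rejects malformed and empty intervals with line numbers", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t0\t100", "chr1\t100\t100"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("chr1\t10"), f)
  expect_error(read_bed(f), "line 1")
})

test_that("BED round trip is identity", {
  f <- withr::local_tempfile()
  df <- data.frame(chrom = c("chr1", "chr2"), start = c(0, 1e6),
                   end = c(5e3, 2e6), name = c("a", "b"), score = c(1.5, 2))
  write_bed(df, f)
  back <- read_bed(f)
  expect_equal(back$start, df$start)
  expect_equal(back$end, df$end)
  expect_equal(back$name, df$name)
  expect_equal(back$score, df$score)
})

test_that("contact matrix canonicalizes: mirroring, duplicate summing, symmetry", {
  fm <- withr::local_tempfile(); fb <- withr::local_tempfile()
  writeLines(c("chr1\t0\t10000\t1", "chr1\t10000\t20000\t2",
               "chr1\t20000\t30000\t3"), fb)
  writeLines(c("2\t1\t3", "1\t2\t4", "1\t3\t5"), fm)
  m <- read_contact_matrix(fm, fb)
  expect_equal(length(m$x), 2)             # (1,2) merged, (1,3)
  expect_equal(m$x[m$i == 1 & m$j == 2], 7)
  D <- hicstates:::cm_dense(m, "chr1")
  expect_equal(D[1, 2], D[2, 1])           # retrievable both ways
  expect_equal(D[3, 1], 5)
  expect_equal(hicstates:::cm_total(m), 12)  # mass conserved
})

test_that("contact matrix rejects bad bin ids and negative counts", {
  fm <- withr::local_tempfile(); fb <- withr::local_tempfile()
  writeLines(c("chr1\t0\t10000\t1", "chr1\t10000\t20000\t2"), fb)
  writeLines("1\t9\t3", fm)
  expect_error(read_contact_matrix(fm, fb), "bin id")
  writeLines("1\t2\t-3", fm)
  expect_error(read_contact_matrix(fm, fb), "negative")
})

test_that("empty triplet file yields a valid empty matrix", {
  fm <- withr::local_tempfile(); fb <- withr::local_tempfile()
  writeLines(c("chr1\t0\t10000\t1", "chr1\t10000\t20000\t2"), fb)
  writeLines(character(0), fm)
  m <- read_contact_matrix(fm, fb)
  expect_equal(length(m$x), 0)
  expect_equal(nrow(m$bins), 2)
})

test_that("contact matrix round trip conserves entries and mass", {
  set.seed(4)
  fl <- flat_bias_matrix(n_bins = 30, lambda0 = 5)
  fm <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_contact_matrix(fl$mat, fm, fb)
  back <- read_contact_matrix(fm, fb)
  expect_equal(hicstates:::cm_total(back), hicstates:::cm_total(fl$mat))
  expect_equal(back$i, fl$mat$i)
  expect_equal(back$x, fl$mat$x, tolerance = 1e-9)
})

test_that("BEDPE round trip preserves loop fields; inter-chromosomal rejected", {
  lp <- toy_loops("chr1", c(1e5, 3e5), c(5e5, 9e5), category = c("PE", "II"))
  f <- withr::local_tempfile()
  write_loops_bedpe(lp, f)
  back <- read_loops_bedpe(f)
  expect_equal(back$start1, lp$start1)
  expect_equal(back$end2, lp$end2)
  expect_equal(back$q, lp$q, tolerance = 1e-6)
  expect_equal(back$category, lp$category)
  bad <- lp
  bad$chrom2 <- c("chr1", "chr2")
  expect_error(write_loops_bedpe(bad, f), "intra-chromosomal")
  bad2 <- lp
  bad2$start1[1] <- NA
  expect_error(write_loops_bedpe(bad2, f), "anchor")
})

test_that("gene table round trip keeps expression columns", {
  g <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1", strand = c("+", "-"),
                  tss = c(1000, 5000), length = c(2000, 3000),
                  normal_rep1 = c(1.5, 0), normal_rep2 = c(2.5, 0.1))
  f <- withr::local_tempfile()
  write_gene_table(g, f)
  back <- read_gene_table(f)
  expect_equal(attr(back, "expr_cols"), c("normal_rep1", "normal_rep2"))
  expect_equal(back$normal_rep2, g$normal_rep2)
  g$length[1] <- 0
  write_gene_table(g, f)
  expect_error(read_gene_table(f), "positive")
})
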