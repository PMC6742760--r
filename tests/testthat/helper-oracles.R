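# Brute-force oracles (plain nested loops, no package internals) and small
# fixture builders shared across the test files.

# Two-sided Fisher exact p by full hypergeometric enumeration: sum of the
# probabilities of all tables (given the margins) no more likely than the
# observed one, with the conventional 1e-7 relative slack on "no more likely".
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  dens <- dhyper(x, m, n, k)
  sum(dens[dens <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Two-sided exact rank-sum p by enumeration of all group assignments
# (midranks), counting assignments at least as far from the null mean.
oracle_ranksum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  center <- nx * (nx + ny + 1) / 2
  obs <- abs(sum(r[1:nx]) - center)
  combos <- combn(nx + ny, nx)
  cnt <- 0
  for (k in seq_len(ncol(combos))) {
    if (abs(sum(r[combos[, k]]) - center) >= obs - 1e-9) cnt <- cnt + 1
  }
  cnt / ncol(combos)
}

# Benjamini-Hochberg step-up by the textbook formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Brute-force pairwise TAD matching by the boundary/reciprocal-overlap rule,
# greedy one-to-one on decreasing reciprocal overlap.
oracle_match_pair <- function(a, b, tol = 80000, min_ov = 0.8) {
  cand <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov <= 0) next
    rec <- min(ov / (a$end[i] - a$start[i]), ov / (b$end[j] - b$start[j]))
    shift <- abs(a$start[i] - b$start[j]) <= tol && abs(a$end[i] - b$end[j]) <= tol
    if (shift || rec >= min_ov) {
      cand[[length(cand) + 1]] <- c(i = i, j = j, rec = rec)
    }
  }
  if (length(cand) == 0) return(data.frame(a = integer(0), b = integer(0)))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, "rec"], cand[, "i"], cand[, "j"]), , drop = FALSE]
  used_a <- used_b <- integer(0)
  out <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, "i"]; j <- cand[k, "j"]
    if (!(i %in% used_a) && !(j %in% used_b)) {
      out[[length(out) + 1]] <- c(i, j)
      used_a <- c(used_a, i); used_b <- c(used_b, j)
    }
  }
  m <- do.call(rbind, out)
  data.frame(a = m[, 1], b = m[, 2])
}

# Random non-overlapping TAD list on one chromosome (bin-aligned).
random_tad_list <- function(n_max = 6, chrom = "chr1", res = 4e4, n_bins = 60) {
  k <- sample(1:n_max, 1)
  edges <- sort(sample(0:n_bins, k + 1))
  while (any(diff(edges) < 2)) edges <- sort(sample(0:n_bins, k + 1))
  data.frame(chrom = chrom, start = edges[-(k + 1)] * res, end = edges[-1] * res)
}

# Dense flat (no-decay) matrix with planted multiplicative bias: the
# canonical balancing testbed where the bias is identifiable.
flat_bias_matrix <- function(n_bins = 300, lambda0 = 50, bias_sd = 0.3,
                             seed = 1, resolution = 1e4) {
  set.seed(seed)
  bins <- make_bin_table(stats::setNames(n_bins * resolution, "chr1"), resolution)
  b <- exp(rnorm(n_bins, 0, bias_sd))
  pr <- which(upper.tri(diag(n_bins), diag = TRUE), arr.ind = TRUE)
  x <- rpois(nrow(pr), lambda0 * b[pr[, 1]] * b[pr[, 2]])
  list(mat = hic_matrix(bins, pr[, 1], pr[, 2], x, resolution), bias = b)
}

# Small uniform constant matrix (all pairs the same count).
constant_matrix <- function(n_bins = 40, value = 5, resolution = 4e4) {
  bins <- make_bin_table(stats::setNames(n_bins * resolution, "chr1"), resolution)
  pr <- which(upper.tri(diag(n_bins), diag = TRUE), arr.ind = TRUE)
  hic_matrix(bins, pr[, 1], pr[, 2], rep(value, nrow(pr)), resolution)
}

# Minimal annotated-loop table builder for anchor/classification tests.
toy_loops <- function(chrom, start1, start2, res = 1e4, category = NULL) {
  n <- length(start1)
  df <- data.frame(chrom = rep(chrom, length.out = n),
                   bin1 = start1 / res + 1, bin2 = start2 / res + 1,
                   start1 = start1, end1 = start1 + res,
                   start2 = start2, end2 = start2 + res,
                   distance = start2 - start1,
                   count = rep(10, n), p = rep(1e-6, n), q = rep(1e-4, n),
                   stringsAsFactors = FALSE)
  if (!is.null(category)) df$category <- category
  df
}
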