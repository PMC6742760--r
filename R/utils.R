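# Shared helpers: interval arithmetic bridges, empirical p-values, weighted
# isotonic regression, and an exact/approximate rank-sum test.

# Convert a 0-based half-open interval data.frame (chrom, start, end) to a
# GRanges (1-based closed) for overlap queries. All user-facing tables in this
# package use 0-based half-open coordinates (the BED convention).
.as_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = pmax(df$end, df$start + 1L))
  )
}

# For each row of `query`, TRUE if it overlaps (>= 1 bp) any row of `subject`.
overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  if (nrow(query) == 0L) return(logical(0))
  suppressWarnings(IRanges::overlapsAny(.as_granges(query), .as_granges(subject)))
}

# Number of rows of `subject` overlapping each row of `query`.
count_overlaps <- function(query, subject) {
  if (nrow(subject) == 0L) return(rep(0L, nrow(query)))
  if (nrow(query) == 0L) return(integer(0))
  suppressWarnings(GenomicRanges::countOverlaps(.as_granges(query), .as_granges(subject)))
}

# Hits between query and subject as a two-column data.frame of row indices.
overlap_pairs <- function(query, subject) {
  if (nrow(subject) == 0L || nrow(query) == 0L) {
    return(data.frame(query = integer(0), subject = integer(0)))
  }
  h <- suppressWarnings(GenomicRanges::findOverlaps(.as_granges(query), .as_granges(subject)))
  data.frame(query = S4Vectors::queryHits(h), subject = S4Vectors::subjectHits(h))
}

# Distance in bp from each query interval to the nearest subject interval
# (0 when overlapping, NA when subject is empty on that chromosome).
distance_to_nearest <- function(query, subject) {
  out <- rep(NA_real_, nrow(query))
  if (nrow(subject) == 0L || nrow(query) == 0L) return(out)
  h <- suppressWarnings(GenomicRanges::distanceToNearest(.as_granges(query), .as_granges(subject)))
  out[S4Vectors::queryHits(h)] <- S4Vectors::mcols(h)$distance
  out
}

#' Empirical p-value with the add-one rule
#'
#' Computes \code{(1 + #\{null >= observed\}) / (n + 1)}, the standard
#' resampling estimator that can never return zero. With 100 null sets an
#' observed statistic exceeding every null value yields p = 1/101 (< 0.01).
#'
#' @param observed observed statistic.
#' @param nulls numeric vector of null statistics.
#' @return empirical p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed, nulls) {
  (1 + sum(nulls >= observed)) / (length(nulls) + 1)
}

# Weighted pool-adjacent-violators for a NON-INCREASING fit. Preserves the
# weighted mean within each pooled block, so sum(fit * w) == sum(y * w).
pava_nonincreasing <- function(y, w = rep(1, length(y))) {
  stopifnot(length(y) == length(w), all(w >= 0))
  n <- length(y)
  if (n == 0L) return(numeric(0))
  # Fit non-increasing y == fit non-decreasing on reversed sequence.
  yr <- rev(y); wr <- rev(w)
  val <- numeric(n); wt <- numeric(n); len <- integer(n)
  m <- 0L
  for (k in seq_len(n)) {
    m <- m + 1L
    val[m] <- yr[k]; wt[m] <- wr[k]; len[m] <- 1L
    while (m > 1L && val[m - 1L] > val[m]) {
      tw <- wt[m - 1L] + wt[m]
      val[m - 1L] <- if (tw > 0) (val[m - 1L] * wt[m - 1L] + val[m] * wt[m]) / tw else
        (val[m - 1L] + val[m]) / 2
      wt[m - 1L] <- tw
      len[m - 1L] <- len[m - 1L] + len[m]
      m <- m - 1L
    }
  }
  rev(rep(val[seq_len(m)], len[seq_len(m)]))
}

#' Rank-sum (Wilcoxon) test with exact permutation enumeration for small groups
#'
#' Two-sided test comparing the distributions of two samples by rank sums.
#' When both groups have at most \code{exact_max} observations the null
#' distribution of the rank sum is enumerated over all group assignments
#' (midranks are used, so ties are handled exactly); otherwise
#' \code{\link[stats]{wilcox.test}} is used.
#'
#' @param x,y numeric vectors.
#' @param exact_max largest per-group size for exhaustive enumeration.
#' @return list with \code{p.value}, \code{statistic} (rank sum of \code{x}),
#'   and \code{method}.
#' @export
ranksum_test <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  if (nx <= exact_max && ny <= exact_max) {
    combos <- utils::combn(nx + ny, nx)
    w_all <- colSums(matrix(r[combos], nrow = nx))
    center <- nx * (nx + ny + 1) / 2
    p <- mean(abs(w_all - center) >= abs(w_obs - center) - 1e-9)
    list(p.value = p, statistic = w_obs, method = "exact permutation rank-sum")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    list(p.value = wt$p.value, statistic = w_obs, method = "wilcoxon rank-sum")
  }
}

# Deterministic substream seed derivation: one root seed, independent named
# stages. Kept below 2^31 - 1.
substream_seed <- function(seed, stage, k = 0L) {
  stage_id <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + stage_id * 1013 + k * 7919) %% 2147483629)
}

# Write a data.frame as a TSV with stable formatting (determinism of outputs).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
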