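# Matrix balancing (ICE), resolution coarsening, and distance-decay
# estimation shared by the TAD and loop callers.

#' ICE (iterative correction) balancing of a contact matrix
#'
#' Iterative proportional fitting of per-bin multiplicative biases: at each
#' step \code{b_i <- b_i * m_i / mean(m)} where \code{m_i} is the current row
#' marginal, until the maximum relative marginal deviation falls below
#' \code{tol} or \code{max_iter} is reached. Bins whose raw marginal falls
#' below the \code{low_coverage_filter} percentile are masked before
#' balancing: their bias is undefined (NA) and their entries are excluded
#' from the normalized matrix and from all downstream analyses.
#'
#' @param mat raw \code{\link{hic_matrix}}.
#' @param max_iter maximum number of iterations (default 200).
#' @param tol convergence tolerance on the maximum relative marginal
#'   deviation (default 1e-4).
#' @param low_coverage_filter fraction of lowest-marginal bins to mask per
#'   chromosome (default 0.02). Bins with marginal strictly below the
#'   percentile value are masked, so a perfectly uniform matrix masks nothing.
#' @return list with \code{matrix} (normalized \code{hic_matrix} carrying the
#'   mask), \code{bias} (per-bin vector, NA for masked bins) and
#'   \code{deviation} (achieved maximum relative marginal deviation).
#' @export
ice_normalize <- function(mat, max_iter = 200, tol = 1e-4,
                          low_coverage_filter = 0.02) {
  n <- nrow(mat$bins)
  bias <- rep(NA_real_, n)
  mask <- rep(FALSE, n)
  new_i <- list(); new_j <- list(); new_x <- list()
  worst_dev <- 0
  for (ch in cm_chroms(mat)) {
    rows <- cm_chrom_rows(mat, ch)
    off <- rows[1] - 1L
    D <- cm_dense(mat, ch)
    marg <- rowSums(D)
    cut <- stats::quantile(marg, low_coverage_filter, names = FALSE, type = 7)
    mk <- marg < cut
    mask[rows[mk]] <- TRUE
    keep <- which(!mk)
    if (length(keep) < 2L) {
      mask[rows] <- TRUE
      next
    }
    Dk <- D[keep, keep, drop = FALSE]
    b <- rep(1, length(keep))
    dev <- Inf
    for (it in seq_len(max_iter)) {
      m <- rowSums(Dk)
      mm <- mean(m)
      if (mm == 0) break
      s <- m / mm
      dev <- max(abs(s - 1))
      if (dev < tol) break
      Dk <- Dk / (s %o% s)
      b <- b * s
    }
    if (dev >= tol && mm > 0) {
      warning(sprintf("ICE did not converge on %s: deviation %.3g after %d iterations",
                      ch, dev, max_iter))
    }
    worst_dev <- max(worst_dev, ifelse(is.finite(dev), dev, 0))
    bias[rows[keep]] <- b
    ut <- which(upper.tri(Dk, diag = TRUE) & Dk > 0, arr.ind = TRUE)
    new_i[[ch]] <- rows[keep[ut[, 1]]]
    new_j[[ch]] <- rows[keep[ut[, 2]]]
    new_x[[ch]] <- Dk[ut]
  }
  norm <- hic_matrix(mat$bins,
                     unlist(new_i, use.names = FALSE),
                     unlist(new_j, use.names = FALSE),
                     unlist(new_x, use.names = FALSE),
                     mat$resolution, bias = bias, mask = mask, normalized = TRUE)
  list(matrix = norm, bias = bias, deviation = worst_dev)
}

#' Coarsen a contact matrix by an integer factor
#'
#' Counts are summed over factor-by-factor blocks of fine bins (e.g. 10 kb to
#' 40 kb with \code{factor = 4}); total mass is conserved exactly. Intended
#' for raw counts before balancing at the coarser resolution.
#'
#' @param mat \code{\link{hic_matrix}} at the fine resolution.
#' @param factor integer >= 2.
#' @return \code{hic_matrix} at \code{resolution * factor}.
#' @export
coarsen <- function(mat, factor) {
  if (length(factor) != 1L || factor != round(factor) || factor < 2) {
    stop("factor must be an integer >= 2")
  }
  factor <- as.integer(factor)
  bins <- mat$bins
  res <- mat$resolution
  chroms <- cm_chroms(mat)
  chrom_sizes <- stats::setNames(
    vapply(chroms, function(ch) max(bins$end[bins$chrom == ch]), numeric(1)),
    chroms)
  cbins <- make_bin_table(chrom_sizes, res * factor)
  # fine row index -> coarse row index
  fine_local <- stats::ave(seq_len(nrow(bins)), bins$chrom, FUN = seq_along) - 1L
  coarse_local <- fine_local %/% factor
  map <- integer(nrow(bins))
  for (ch in chroms) {
    fsel <- bins$chrom == ch
    csel <- which(cbins$chrom == ch)
    map[fsel] <- csel[coarse_local[fsel] + 1L]
  }
  hic_matrix(cbins, map[mat$i], map[mat$j], mat$x, res * factor)
}

#' Estimate the distance-decay contact probability profile
#'
#' For each genomic-distance stratum d the expected per-pair contact
#' probability is \code{p_d = sum(counts at d) / (N_total * M_d)}, where
#' \code{M_d} counts all locus pairs at that distance (zero-count pairs
#' included) and \code{N_total} is the total in-range contact count. Exact
#' bin-distance strata are used up to \code{max_exact} bins and log-spaced
#' strata beyond; the profile is then smoothed with weighted non-increasing
#' isotonic regression, which also fills empty strata from their neighbours.
#' By construction \code{sum(p_d * M_d) == 1} over the in-range pairs.
#'
#' @param mat normalized \code{\link{hic_matrix}} (masked bins excluded).
#' @param range numeric length-2, genomic distance range in bp
#'   (default 50 kb to 10 Mb).
#' @param max_exact largest bin distance given its own stratum (default 200).
#' @param n_log_strata number of log-spaced strata past \code{max_exact}.
#' @param smooth apply the isotonic smoothing (default TRUE).
#' @return object of class \code{decay_profile}: a list with the stratum
#'   table, \code{N_total} and \code{resolution}.
#' @export
estimate_decay <- function(mat, range = c(5e4, 1e7), max_exact = 200,
                           n_log_strata = 25, smooth = TRUE) {
  res <- mat$resolution
  d_lo <- as.integer(ceiling(range[1] / res))
  d_hi_chrom <- vapply(cm_chroms(mat), function(ch) length(cm_chrom_rows(mat, ch)) - 1L,
                       integer(1))
  d_hi <- min(as.integer(floor(range[2] / res)), max(d_hi_chrom))
  if (d_hi < d_lo) stop("no bin pairs in the requested distance range")
  breaks <- seq(d_lo, min(max_exact, d_hi) + 1L)
  if (d_hi > max_exact) {
    lg <- unique(round(exp(seq(log(max_exact + 1), log(d_hi + 1),
                               length.out = n_log_strata + 1L))))
    breaks <- c(breaks[-length(breaks)], lg)
  }
  lower <- breaks[-length(breaks)]
  upper <- breaks[-1] - 1L        # inclusive
  upper[length(upper)] <- d_hi
  nstrat <- length(lower)
  stratum_of <- function(d) findInterval(d, lower)

  counts <- numeric(nstrat)
  pairs <- numeric(nstrat)
  for (ch in cm_chroms(mat)) {
    rows <- cm_chrom_rows(mat, ch)
    n <- length(rows)
    u <- if (is.null(mat$mask)) rep(TRUE, n) else !mat$mask[rows]
    sel <- mat$i >= rows[1] & mat$i <= rows[n]
    sel[sel] <- u[mat$i[sel] - rows[1] + 1L] & u[mat$j[sel] - rows[1] + 1L]
    d <- mat$j[sel] - mat$i[sel]
    inr <- d >= d_lo & d <= d_hi
    if (any(inr)) {
      s <- stratum_of(d[inr])
      agg <- rowsum(mat$x[sel][inr], s)
      counts[as.integer(rownames(agg))] <-
        counts[as.integer(rownames(agg))] + agg[, 1]
    }
    for (d in seq(d_lo, min(d_hi, n - 1L))) {
      np <- sum(u[seq_len(n - d)] & u[seq(d + 1L, n)])
      k <- stratum_of(d)
      pairs[k] <- pairs[k] + np
    }
  }
  N_total <- sum(counts)
  if (N_total <= 0) stop("no contacts in the requested distance range")
  phat_raw <- ifelse(pairs > 0, counts / (N_total * pairs), NA_real_)
  phat <- phat_raw
  if (smooth) {
    y <- ifelse(is.na(phat_raw), 0, phat_raw)
    w <- pairs
    phat <- pava_nonincreasing(y, w)
    # strata with no pairs inherit the pooled neighbour value
    if (anyNA(phat_raw)) {
      fit <- phat
      empty <- which(pairs == 0)
      for (k in empty) {
        nb <- which(pairs > 0)
        fit[k] <- phat[nb[which.min(abs(nb - k))]]
      }
      phat <- fit
    }
  } else {
    phat[is.na(phat)] <- 0
  }
  structure(list(
    strata = data.frame(stratum = seq_len(nstrat), d_lo = lower, d_hi = upper,
                        pairs = pairs, count = counts,
                        phat_raw = phat_raw, phat = phat),
    N_total = N_total, resolution = res, d_range = c(d_lo, d_hi)),
    class = "decay_profile")
}

#' Look up expected contact probabilities for bin distances
#' @param decay a \code{decay_profile}.
#' @param d integer vector of bin distances.
#' @return expected per-pair contact probability for each distance.
#' @export
decay_prob <- function(decay, d) {
  k <- findInterval(d, decay$strata$d_lo)
  out <- rep(NA_real_, length(d))
  ok <- k >= 1 & d <= decay$strata$d_hi[pmax(k, 1)]
  out[ok] <- decay$strata$phat[k[ok]]
  out
}

#' @export
print.decay_profile <- function(x, ...) {
  cat(sprintf("decay_profile: %d strata, bin distances %d-%d, N_total %.4g\n",
              nrow(x$strata), x$d_range[1], x$d_range[2], x$N_total))
  invisible(x)
}
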