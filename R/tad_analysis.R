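# Diamond-statistic (TopDom-style) TAD calling on coarse-binned normalized
# matrices, cross-cell-line TAD matching and classification, size statistics,
# and split-TAD detection.

#' Call TADs with the diamond (binSignal) statistic
#'
#' The matrix is first distance-normalized: every entry is divided by the
#' chromosome's mean count at its bin distance (observed/expected), which
#' cancels the distance decay so the boundary statistics compare structure,
#' not genomic separation. On that normalized matrix, the bin signal at the
#' boundary between bins i and i+1 is the mean of the w-by-w diamond
#' submatrix spanning bins (i-w+1..i) versus (i+1..i+w), truncated at
#' chromosome ends. Candidate boundaries are local minima of the bin signal
#' relative to a least-squares linear trend fitted within +/- w bins, and
#' each candidate is retained when a one-sided rank-sum test finds the
#' cross-boundary diamond entries significantly smaller than the pooled
#' within-side upper-triangle entries (windows of w). Domains are the
#' intervals between consecutive retained boundaries, with a minimum size of
#' two bins. Runs of at least \code{gap_bins} masked bins break domains;
#' shorter masked runs are bridged (the diamond mean simply ignores missing
#' entries).
#'
#' @param mat normalized coarse-resolution \code{\link{hic_matrix}}
#'   (typically 40 kb).
#' @param window diamond half-width w in bins (default 5).
#' @param p_cutoff boundary rank-sum p-value cutoff (default 0.05).
#' @param gap_bins minimum masked-run length that splits domains (default 3).
#' @return data.frame of TADs: \code{chrom}, \code{start}, \code{end} (bp, on
#'   bin edges), \code{size}; attribute \code{"boundaries"} holds the retained
#'   boundary table.
#' @export
call_tads <- function(mat, window = 5, p_cutoff = 0.05, gap_bins = 3) {
  w <- as.integer(window)
  stopifnot(w >= 2)
  res <- mat$resolution
  tads <- list()
  bounds <- list()
  for (ch in cm_chroms(mat)) {
    rows <- cm_chrom_rows(mat, ch)
    n <- length(rows)
    chrom_start <- mat$bins$start[rows[1]]
    if (n < 2 * w) {
      warning(sprintf("chromosome %s shorter than 2*window bins; no TADs called", ch))
      next
    }
    D <- cm_dense(mat, ch)
    masked <- if (is.null(mat$mask)) rep(FALSE, n) else mat$mask[rows]
    # observed/expected: divide each entry by the mean count at its distance
    for (d in 0:(n - 1L)) {
      idx <- seq_len(n - d)
      v <- D[cbind(idx, idx + d)]
      ed <- mean(v, na.rm = TRUE)
      if (!is.finite(ed) || ed <= 0) next
      D[cbind(idx, idx + d)] <- v / ed
      if (d > 0L) D[cbind(idx + d, idx)] <- D[cbind(idx, idx + d)]
    }

    # maximal blocks of usable bins: masked runs >= gap_bins split blocks
    r <- rle(masked)
    hard_gap <- rep(r$values & r$lengths >= gap_bins, r$lengths)
    blocks <- split(seq_len(n), cumsum(c(TRUE, diff(hard_gap) != 0)))
    blocks <- Filter(function(ix) !hard_gap[ix[1]] && sum(!masked[ix]) >= 2 * w, blocks)

    for (blk in blocks) {
      b0 <- blk[1]; b1 <- blk[length(blk)]
      nb <- b1 - b0 + 1L
      # bin signal at boundary after local bin b (1 .. nb-1)
      sig <- rep(NA_real_, nb - 1L)
      for (b in seq_len(nb - 1L)) {
        i <- b0 + b - 1L
        rws <- max(b0, i - w + 1L):i
        cls <- (i + 1L):min(b1, i + w)
        v <- D[rws, cls, drop = FALSE]
        sig[b] <- mean(v, na.rm = TRUE)
      }
      if (all(is.na(sig))) next
      # residual from a local least-squares linear trend within +/- w
      resid <- rep(NA_real_, length(sig))
      for (b in seq_along(sig)) {
        idx <- max(1L, b - w):min(length(sig), b + w)
        ok <- idx[!is.na(sig[idx])]
        if (length(ok) < 3L || is.na(sig[b])) next
        cf <- stats::lm.fit(cbind(1, ok), sig[ok])$coefficients
        resid[b] <- sig[b] - (cf[1] + cf[2] * b)
      }
      cand <- integer(0)
      for (b in seq_along(resid)) {
        if (is.na(resid[b]) || resid[b] >= 0) next
        left <- if (b > 1L) resid[b - 1L] else Inf
        right <- if (b < length(resid)) resid[b + 1L] else Inf
        if (!is.na(left) && resid[b] > left) next
        if (!is.na(right) && resid[b] > right) next
        cand <- c(cand, b)
      }
      kept <- data.frame(b = integer(0), p = numeric(0))
      for (b in cand) {
        i <- b0 + b - 1L
        rws <- max(b0, i - w + 1L):i
        cls <- (i + 1L):min(b1, i + w)
        cross <- as.numeric(D[rws, cls])
        wl <- D[rws, rws, drop = FALSE]
        wr <- D[cls, cls, drop = FALSE]
        within <- c(wl[upper.tri(wl)], wr[upper.tri(wr)])
        cross <- cross[!is.na(cross)]; within <- within[!is.na(within)]
        if (length(cross) < 2L || length(within) < 2L) next
        p <- suppressWarnings(stats::wilcox.test(cross, within,
                                                 alternative = "less")$p.value)
        if (!is.na(p) && p < p_cutoff) kept <- rbind(kept, data.frame(b = b, p = p))
      }
      # enforce minimum domain size of 2 bins: of two boundaries closer than
      # 2 bins, keep the one with the smaller p
      if (nrow(kept) > 1L) {
        kept <- kept[order(kept$b), ]
        repeat {
          gaps <- diff(kept$b)
          viol <- which(gaps < 2L)
          if (length(viol) == 0L) break
          v <- viol[1]
          drop <- if (kept$p[v] <= kept$p[v + 1L]) v + 1L else v
          kept <- kept[-drop, ]
        }
      }
      edges <- c(b0 - 1L, kept$b + b0 - 1L, b1)  # bin indices ending each domain
      edges <- unique(edges)
      for (k in seq_len(length(edges) - 1L)) {
        lo <- edges[k] + 1L; hi <- edges[k + 1L]
        if (hi - lo + 1L < 2L) next
        tads[[length(tads) + 1L]] <- data.frame(
          chrom = ch,
          start = chrom_start + (lo - 1L) * res,
          end = chrom_start + hi * res,
          stringsAsFactors = FALSE)
      }
      if (nrow(kept) > 0L) {
        bounds[[length(bounds) + 1L]] <- data.frame(
          chrom = ch, pos = chrom_start + (kept$b + b0 - 1L) * res, p = kept$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(tads) > 0L) do.call(rbind, tads) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  out$size <- out$end - out$start
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "boundaries") <- if (length(bounds) > 0L) do.call(rbind, bounds) else
    data.frame(chrom = character(0), pos = numeric(0), p = numeric(0))
  attr(out, "resolution") <- res
  out
}

# Pairwise TAD matching: A and B match when both boundary shifts are within
# tol_bp OR the reciprocal overlap is >= min_overlap of BOTH TADs. Returns a
# one-to-one matching (greedy on decreasing reciprocal overlap).
.match_tad_pair <- function(a, b, tol_bp = 80000, min_overlap = 0.8) {
  hits <- overlap_pairs(a, b)
  if (nrow(hits) == 0L) return(data.frame(a = integer(0), b = integer(0)))
  ia <- hits$query; ib <- hits$subject
  same_chrom <- a$chrom[ia] == b$chrom[ib]
  ov <- pmax(0, pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib]))
  rec <- pmin(ov / (a$end[ia] - a$start[ia]), ov / (b$end[ib] - b$start[ib]))
  shift_ok <- abs(a$start[ia] - b$start[ib]) <= tol_bp &
    abs(a$end[ia] - b$end[ib]) <= tol_bp
  ok <- same_chrom & (shift_ok | rec >= min_overlap)
  ia <- ia[ok]; ib <- ib[ok]; rec <- rec[ok]
  o <- order(-rec, ia, ib)
  ia <- ia[o]; ib <- ib[o]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(length(ia))
  for (k in seq_along(ia)) {
    if (!used_a[ia[k]] && !used_b[ib[k]]) {
      keep[k] <- TRUE; used_a[ia[k]] <- TRUE; used_b[ib[k]] <- TRUE
    }
  }
  data.frame(a = ia[keep], b = ib[keep])
}

.check_tads_nonoverlapping <- function(tads, label) {
  for (ch in unique(tads$chrom)) {
    t <- tads[tads$chrom == ch, ]
    t <- t[order(t$start), ]
    if (nrow(t) > 1L && any(t$start[-1] < t$end[-nrow(t)])) {
      stop("overlapping TADs within cell line ", label)
    }
  }
  invisible(TRUE)
}

#' Match TADs across three cell lines and classify them
#'
#' Two TADs from different lines match when both boundary shifts are at most
#' \code{tol_bp} (80 kb, two 40 kb bins) or when they reciprocally overlap at
#' least \code{min_overlap} of both lengths. Matching within a line pair is
#' one-to-one, resolved greedily by decreasing reciprocal overlap. A TAD chain
#' is \emph{common} when all three pairwise matches close a triangle,
#' \emph{normal-specific} when a normal TAD matches neither cancer line, and
#' \emph{cancer-specific} when the two cancer lines match each other and
#' neither member matches a normal TAD; everything else is \emph{other}.
#'
#' @param tads_by_line named list of three TAD data.frames; the first element
#'   is the normal line, the remaining two the cancer lines.
#' @param tol_bp boundary tolerance in bp (default 80000).
#' @param min_overlap reciprocal overlap fraction (default 0.8).
#' @return object of class \code{tad_classification}: list with \code{chains}
#'   (one row per classified TAD entity: class, member indices, mean size)
#'   and \code{labels} (per-line vectors of per-TAD labels).
#' @export
match_tads <- function(tads_by_line, tol_bp = 80000, min_overlap = 0.8) {
  stopifnot(length(tads_by_line) == 3L)
  nms <- names(tads_by_line)
  if (is.null(nms)) nms <- c("normal", "cancer1", "cancer2")
  for (k in 1:3) .check_tads_nonoverlapping(tads_by_line[[k]], nms[k])
  tn <- tads_by_line[[1]]; tc1 <- tads_by_line[[2]]; tc2 <- tads_by_line[[3]]
  m_n1 <- .match_tad_pair(tn, tc1, tol_bp, min_overlap)
  m_n2 <- .match_tad_pair(tn, tc2, tol_bp, min_overlap)
  m_12 <- .match_tad_pair(tc1, tc2, tol_bp, min_overlap)
  map_n1 <- rep(NA_integer_, nrow(tn)); map_n1[m_n1$a] <- m_n1$b
  map_n2 <- rep(NA_integer_, nrow(tn)); map_n2[m_n2$a] <- m_n2$b
  map_12 <- rep(NA_integer_, nrow(tc1)); map_12[m_12$a] <- m_12$b
  matched_n1_b <- rep(FALSE, nrow(tc1)); matched_n1_b[m_n1$b] <- TRUE
  matched_n2_b <- rep(FALSE, nrow(tc2)); matched_n2_b[m_n2$b] <- TRUE
  matched_12_b <- rep(FALSE, nrow(tc2)); matched_12_b[m_12$b] <- TRUE

  lab_n <- rep("other", nrow(tn))
  lab_1 <- rep("other", nrow(tc1))
  lab_2 <- rep("other", nrow(tc2))
  chains <- list()
  # common: triangle closes
  for (a in seq_len(nrow(tn))) {
    b <- map_n1[a]; c2 <- map_n2[a]
    if (!is.na(b) && !is.na(c2) && !is.na(map_12[b]) && map_12[b] == c2) {
      lab_n[a] <- "common"; lab_1[b] <- "common"; lab_2[c2] <- "common"
      chains[[length(chains) + 1L]] <- data.frame(
        class = "common", chrom = tn$chrom[a],
        normal_idx = a, cancer1_idx = b, cancer2_idx = c2,
        size = mean(c(tn$end[a] - tn$start[a], tc1$end[b] - tc1$start[b],
                      tc2$end[c2] - tc2$start[c2])), stringsAsFactors = FALSE)
    }
  }
  # normal-specific: unmatched in both cancer lines
  for (a in seq_len(nrow(tn))) {
    if (is.na(map_n1[a]) && is.na(map_n2[a])) {
      lab_n[a] <- "normal_specific"
      chains[[length(chains) + 1L]] <- data.frame(
        class = "normal_specific", chrom = tn$chrom[a],
        normal_idx = a, cancer1_idx = NA_integer_, cancer2_idx = NA_integer_,
        size = tn$end[a] - tn$start[a], stringsAsFactors = FALSE)
    }
  }
  # cancer-specific: cancer pair matched, neither matched to normal
  for (b in seq_len(nrow(tc1))) {
    c2 <- map_12[b]
    if (!is.na(c2) && !matched_n1_b[b] && !matched_n2_b[c2]) {
      lab_1[b] <- "cancer_specific"; lab_2[c2] <- "cancer_specific"
      chains[[length(chains) + 1L]] <- data.frame(
        class = "cancer_specific", chrom = tc1$chrom[b],
        normal_idx = NA_integer_, cancer1_idx = b, cancer2_idx = c2,
        size = mean(c(tc1$end[b] - tc1$start[b], tc2$end[c2] - tc2$start[c2])),
        stringsAsFactors = FALSE)
    }
  }
  chains <- if (length(chains) > 0L) do.call(rbind, chains) else
    data.frame(class = character(0), chrom = character(0),
               normal_idx = integer(0), cancer1_idx = integer(0),
               cancer2_idx = integer(0), size = numeric(0))
  structure(list(chains = chains,
                 labels = stats::setNames(list(lab_n, lab_1, lab_2), nms),
                 tads = stats::setNames(list(tn, tc1, tc2), nms),
                 counts = table(factor(chains$class,
                                       levels = c("common", "normal_specific",
                                                  "cancer_specific")))),
            class = "tad_classification")
}

#' @export
print.tad_classification <- function(x, ...) {
  cat("tad_classification:\n")
  print(x$counts)
  invisible(x)
}

#' Compare TAD sizes between classification groups
#'
#' Pairwise two-sided rank-sum tests on the size distributions of the
#' common, normal-specific and cancer-specific TAD entities, with
#' Benjamini-Hochberg adjustment across the comparisons.
#'
#' @param classification a \code{tad_classification}.
#' @return data.frame with group pair, medians, rank-sum p and BH-adjusted p.
#' @export
compare_tad_sizes <- function(classification) {
  ch <- classification$chains
  groups <- split(ch$size, ch$class)
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) < 2L) stop("need at least two groups with >= 2 TADs")
  pairs <- utils::combn(names(groups), 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    tst <- ranksum_test(groups[[g1]], groups[[g2]])
    data.frame(group1 = g1, group2 = g2,
               median1 = stats::median(groups[[g1]]),
               median2 = stats::median(groups[[g2]]),
               p = tst$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Detect normal TADs split into several cancer TADs
#'
#' A normal TAD N is reported as split when at least two cancer TADs each lie
#' inside N with at least \code{min_overlap} of their own length, and together
#' those children cover at least \code{min_overlap} of N.
#'
#' @param normal_tads,cancer_tads TAD data.frames.
#' @param min_overlap containment/coverage fraction (default 0.8).
#' @param genes optional gene table; genes with TSS inside each split parent
#'   are listed.
#' @return data.frame with one row per split parent: coordinates, number of
#'   children, child indices (comma-separated), and gene ids when supplied.
#' @export
detect_split_tads <- function(normal_tads, cancer_tads, min_overlap = 0.8,
                              genes = NULL) {
  out <- list()
  hits <- overlap_pairs(normal_tads, cancer_tads)
  for (a in unique(hits$query)) {
    kids <- hits$subject[hits$query == a]
    ns <- normal_tads$start[a]; ne <- normal_tads$end[a]
    ov <- pmax(0, pmin(ne, cancer_tads$end[kids]) - pmax(ns, cancer_tads$start[kids]))
    frac_child <- ov / (cancer_tads$end[kids] - cancer_tads$start[kids])
    kids <- kids[frac_child >= min_overlap]
    ov <- ov[frac_child >= min_overlap]
    if (length(kids) >= 2L && sum(ov) / (ne - ns) >= min_overlap) {
      gene_ids <- ""
      if (!is.null(genes)) {
        inside <- genes$chrom == normal_tads$chrom[a] & genes$tss >= ns & genes$tss < ne
        gene_ids <- paste(genes$gene_id[inside], collapse = ",")
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = normal_tads$chrom[a], start = ns, end = ne,
        n_children = length(kids),
        children = paste(sort(kids), collapse = ","),
        genes = gene_ids, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      n_children = integer(0), children = character(0),
                      genes = character(0)))
  }
  do.call(rbind, out)
}
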