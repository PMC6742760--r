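# Histone-mark TAD-state annotation, gene-density classes, the random-TAD
# empirical null, and state-change detection on common TADs.

#' Length-weighted mean of a binned signal track per TAD
#'
#' @param tads TAD data.frame (\code{chrom}, \code{start}, \code{end}).
#' @param track binned signal data.frame (\code{chrom}, \code{start},
#'   \code{end}, \code{value}), bedGraph-like.
#' @return numeric vector of per-TAD means, weighted by covered bp; TADs with
#'   no coverage get 0 and are flagged in the \code{"uncovered"} attribute.
#' @export
mean_signal_per_tad <- function(tads, track) {
  out <- numeric(nrow(tads))
  uncovered <- logical(nrow(tads))
  hits <- overlap_pairs(tads, track)
  if (nrow(hits) > 0L) {
    ov <- pmin(tads$end[hits$query], track$end[hits$subject]) -
      pmax(tads$start[hits$query], track$start[hits$subject])
    wsum <- rowsum(ov * track$value[hits$subject], hits$query)
    w <- rowsum(ov, hits$query)
    idx <- as.integer(rownames(wsum))
    out[idx] <- wsum[, 1] / w[, 1]
  }
  uncovered[setdiff(seq_len(nrow(tads)), unique(hits$query))] <- TRUE
  attr(out, "uncovered") <- uncovered
  out
}

# Top peaks for enrichment calls: rank by score (descending, ties broken by
# coordinate) and take min(top_n, ceiling(frac * total)).
top_peaks <- function(peaks, top_n = 30000, frac = 0.25) {
  if (nrow(peaks) == 0L) return(peaks)
  if (nrow(peaks) < top_n) {
    warning(sprintf("only %d peaks available (top_n = %d); using the top fraction",
                    nrow(peaks), top_n))
  }
  score <- if ("score" %in% names(peaks)) peaks$score else rep(0, nrow(peaks))
  o <- order(-score, peaks$chrom, peaks$start)
  k <- min(top_n, ceiling(frac * nrow(peaks)))
  peaks[o[seq_len(k)], , drop = FALSE]
}

#' Classify TAD chromatin states from histone-mark peaks and signal
#'
#' A TAD is \emph{enriched} for a mark when it intersects at least one
#' top-ranked peak of that mark AND its mean signal is at or above the
#' \code{signal_quantile} percentile of per-TAD means for that mark. The
#' top-ranked peak set is the strongest \code{min(top_n, ceiling(0.25 * n))}
#' peaks by score. When several marks are enriched the state label follows
#' the precedence H3K36me3 > H3K27me3 > H3K9me3 (the active mark wins); TADs
#' enriched for no mark are labelled \code{other}. Raw per-mark flags are
#' retained alongside the label.
#'
#' @param tads TAD data.frame.
#' @param peak_sets named list of peak data.frames (one per mark, with a
#'   \code{score} column).
#' @param signal_tracks named list of binned signal tracks (same mark names).
#' @param top_n peak-count cap (default 30000).
#' @param signal_quantile per-TAD mean-signal quantile (default 0.75).
#' @return data.frame: the TADs plus per-mark \code{<mark>_peaks},
#'   \code{<mark>_signal}, \code{<mark>_enriched} columns and a \code{state}
#'   label.
#' @export
classify_tad_states <- function(tads, peak_sets, signal_tracks,
                                top_n = 30000, signal_quantile = 0.75) {
  out <- tads
  marks <- names(peak_sets)
  enr <- matrix(FALSE, nrow(tads), length(marks), dimnames = list(NULL, marks))
  for (mk in marks) {
    tp <- top_peaks(peak_sets[[mk]], top_n = top_n)
    cnt <- count_overlaps(tads, tp)
    sig <- mean_signal_per_tad(tads, signal_tracks[[mk]])
    thr <- stats::quantile(sig, signal_quantile, names = FALSE, type = 7)
    enr[, mk] <- cnt >= 1L & sig >= thr
    out[[paste0(mk, "_peaks")]] <- cnt
    out[[paste0(mk, "_signal")]] <- as.numeric(sig)
    out[[paste0(mk, "_enriched")]] <- enr[, mk]
  }
  precedence <- intersect(c("H3K36me3", "H3K27me3", "H3K9me3"), marks)
  precedence <- c(precedence, setdiff(marks, precedence))
  state <- rep("other", nrow(tads))
  for (mk in rev(precedence)) state[enr[, mk]] <- mk
  out$state <- state
  out
}

#' Gene-density class per TAD
#'
#' Genes are assigned to a TAD when their TSS lies inside it. 0 genes =
#' \code{desert}; 1-5 genes = \code{poor}; more than 5 = \code{enriched}.
#'
#' @param tads TAD data.frame.
#' @param genes gene table with \code{chrom} and \code{tss}.
#' @return character vector of classes, with gene counts in the
#'   \code{"n_genes"} attribute.
#' @export
gene_density_class <- function(tads, genes) {
  tss <- data.frame(chrom = genes$chrom, start = genes$tss, end = genes$tss + 1)
  cnt <- count_overlaps(tads, tss)
  cls <- cut(cnt, breaks = c(-1, 0, 5, Inf), labels = c("desert", "poor", "enriched"))
  out <- as.character(cls)
  attr(out, "n_genes") <- cnt
  out
}

#' Random-TAD empirical null for histone-mark enrichment
#'
#' Generates \code{n_sets} sets of random non-overlapping TAD-sized intervals
#' (sizes uniform in \code{size_range}), counts how many random TADs are
#' called enriched by \code{enrich_count}, and returns the add-one empirical
#' p-value \code{(1 + #\{null >= observed\}) / (n_sets + 1)} for the observed
#' enriched-TAD count.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param n_tads number of random TADs per set.
#' @param enrich_count function taking a TAD data.frame and returning the
#'   number of enriched TADs in it.
#' @param observed observed enriched-TAD count from the real TADs.
#' @param n_sets number of random sets (default 100).
#' @param size_range TAD size range in bp (default 280-440 kb).
#' @param seed integer seed.
#' @return list with \code{p}, \code{observed}, and \code{null_counts}.
#' @export
random_tad_null <- function(chrom_sizes, n_tads, enrich_count, observed,
                            n_sets = 100, size_range = c(280000, 440000),
                            seed = 1) {
  if (sum(chrom_sizes) < n_tads * max(size_range) * 1.5) {
    stop("genome too small to place a non-overlapping random TAD set")
  }
  null_counts <- integer(n_sets)
  for (s in seq_len(n_sets)) {
    set.seed(substream_seed(seed, "random_tad_null", s))
    tads <- random_intervals(chrom_sizes, n_tads, size_range)
    null_counts[s] <- enrich_count(tads)
  }
  list(p = empirical_pvalue(observed, null_counts), observed = observed,
       null_counts = null_counts)
}

# Place n non-overlapping intervals with sizes uniform in size_range,
# uniformly across chromosomes (rejection sampling).
random_intervals <- function(chrom_sizes, n, size_range) {
  chroms <- names(chrom_sizes)
  placed <- vector("list", n)
  occupied <- lapply(chroms, function(ch) data.frame(start = numeric(0), end = numeric(0)))
  names(occupied) <- chroms
  tries <- 0L
  k <- 0L
  while (k < n) {
    tries <- tries + 1L
    if (tries > n * 200L) stop("could not place non-overlapping random intervals")
    size <- round(stats::runif(1, size_range[1], size_range[2]))
    ch <- sample(chroms, 1, prob = as.numeric(chrom_sizes))
    if (chrom_sizes[[ch]] <= size) next
    st <- floor(stats::runif(1, 0, chrom_sizes[[ch]] - size))
    occ <- occupied[[ch]]
    if (nrow(occ) > 0L && any(st < occ$end & st + size > occ$start)) next
    k <- k + 1L
    occupied[[ch]] <- rbind(occ, data.frame(start = st, end = st + size))
    placed[[k]] <- data.frame(chrom = ch, start = st, end = st + size,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, placed)
  out$size <- out$end - out$start
  rownames(out) <- NULL
  out
}

#' Detect epigenetic state changes in common TADs
#'
#' A common TAD is \emph{changed} when its state label differs between the
#' two conditions. Per initial (normal) state group the fraction changed is
#' reported, and each pair of groups is compared with a two-sided Fisher
#' exact test on the changed/unchanged 2x2 table, BH-adjusted.
#'
#' @param ann_normal,ann_cancer state annotations (from
#'   \code{\link{classify_tad_states}}) of the SAME common TAD intervals in
#'   the two conditions (row-aligned).
#' @param genes optional gene table; genes in changed TADs are listed.
#' @param fold_changes optional named vector of per-gene log2 fold changes to
#'   attach to the gene lists.
#' @return list with \code{tads} (per-TAD states + changed flag),
#'   \code{fractions} (per initial state), \code{tests} (pairwise Fisher),
#'   and \code{changed_genes}.
#' @export
detect_state_changes <- function(ann_normal, ann_cancer, genes = NULL,
                                 fold_changes = NULL) {
  stopifnot(nrow(ann_normal) == nrow(ann_cancer))
  changed <- ann_normal$state != ann_cancer$state
  tads <- data.frame(chrom = ann_normal$chrom, start = ann_normal$start,
                     end = ann_normal$end,
                     state_normal = ann_normal$state,
                     state_cancer = ann_cancer$state,
                     changed = changed, stringsAsFactors = FALSE)
  grp <- split(changed, ann_normal$state)
  grp <- grp[lengths(grp) > 0L]
  fractions <- data.frame(state = names(grp),
                          n = lengths(grp),
                          n_changed = vapply(grp, sum, integer(1)),
                          fraction_changed = vapply(grp, mean, numeric(1)),
                          row.names = NULL, stringsAsFactors = FALSE)
  tests <- NULL
  if (length(grp) >= 2L) {
    pairs <- utils::combn(names(grp), 2)
    res <- lapply(seq_len(ncol(pairs)), function(k) {
      g1 <- grp[[pairs[1, k]]]; g2 <- grp[[pairs[2, k]]]
      tab <- matrix(c(sum(g1), sum(!g1), sum(g2), sum(!g2)), 2, byrow = TRUE)
      data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
                 p = stats::fisher.test(tab)$p.value, stringsAsFactors = FALSE)
    })
    tests <- do.call(rbind, res)
    tests$adj_p <- stats::p.adjust(tests$p, method = "BH")
  }
  changed_genes <- NULL
  if (!is.null(genes)) {
    ct <- tads[tads$changed, , drop = FALSE]
    tss <- data.frame(chrom = genes$chrom, start = genes$tss, end = genes$tss + 1)
    hit <- overlap_pairs(tss, ct)
    changed_genes <- data.frame(
      gene_id = genes$gene_id[hit$query],
      chrom = ct$chrom[hit$subject],
      tad_start = ct$start[hit$subject], tad_end = ct$end[hit$subject],
      state_normal = ct$state_normal[hit$subject],
      state_cancer = ct$state_cancer[hit$subject], stringsAsFactors = FALSE)
    if (!is.null(fold_changes)) {
      changed_genes$log2fc <- as.numeric(fold_changes[changed_genes$gene_id])
    }
  }
  list(tads = tads, fractions = fractions, tests = tests,
       changed_genes = changed_genes)
}
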