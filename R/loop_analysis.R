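# Distance-stratified chromatin-loop significance at fine (10 kb) resolution,
# sequential promoter/enhancer/insulator anchor annotation, loop-fate
# fractions, shuffle nulls, cross-cell-line enhancer-promoter loop
# classification, differential loop tests, and TF/NDR anchor intersections.

#' Call significant chromatin loops against the distance-decay null
#'
#' For every intra-chromosomal bin pair in the distance range, the observed
#' raw count k (reconstructed as normalized count times the bin bias
#' product) is tested against \code{X ~ Binomial(N_total, p_d * b_i * b_j)}
#' where p_d is the stratum contact probability and b the per-bin bias (the
#' bias-aware refined null). The reported p-value is the mid-p tail
#' \code{P(X > k) + P(X = k)/2}: the plain tail \code{P(X >= k)} of a
#' discrete statistic has null mean above 1/2 and would be systematically
#' conservative at moderate expected counts, while the mid-p null
#' distribution is calibrated to uniform (verified on simulated nulls; in
#' the far tail that decides significance the two definitions agree to
#' within a factor of two). Benjamini-Hochberg
#' adjustment runs over ALL in-range pairs (zero-count pairs included), and
#' loops are the pairs with \code{q < q_cutoff}. Masked bins are excluded.
#'
#' Matrix balancing identifies bias only up to the balancing factors of the
#' distance structure itself: balancing \code{diag(b) M diag(b)} returns
#' \code{b} times the balancing factors of M, which deviate from 1 near
#' chromosome ends (edge bins genuinely see fewer close partners). Using the
#' raw ICE bias in the null would therefore misstate expected counts near
#' the ends. The caller removes this deterministic edge factor exactly: it
#' balances the expected distance-profile matrix (mean observed count at
#' each bin distance), divides the ICE bias by those structure-only factors,
#' and re-estimates the stratum probabilities with the corrected bias before
#' testing.
#'
#' @param mat normalized fine-resolution \code{\link{hic_matrix}}.
#' @param decay \code{decay_profile} estimated on the same matrix.
#' @param q_cutoff BH q-value cutoff (default 0.05).
#' @param range genomic distance range in bp (default 50 kb - 10 Mb).
#' @param return_pvalues also return the full p-value vector over all
#'   in-range pairs (for calibration checks).
#' @return data.frame of loops: \code{chrom}, \code{bin1}, \code{bin2}
#'   (chromosome-local bin numbers), anchor coordinates, \code{distance},
#'   \code{count}, \code{p}, \code{q}; attributes \code{"n_tests"} and
#'   optionally \code{"pvalues"}.
#' @export
call_significant_loops <- function(mat, decay, q_cutoff = 0.05,
                                   range = c(5e4, 1e7),
                                   return_pvalues = FALSE) {
  res <- mat$resolution
  N <- round(decay$N_total)
  if (N <= 0) stop("decay profile has zero total contact count")
  acc <- list()
  d_lo <- as.integer(ceiling(range[1] / res))
  d_hi <- as.integer(floor(range[2] / res))
  for (ch in cm_chroms(mat)) {
    rows <- cm_chrom_rows(mat, ch)
    n <- length(rows)
    u <- if (is.null(mat$mask)) rep(TRUE, n) else !mat$mask[rows]
    bb <- if (is.null(mat$bias)) rep(1, n) else mat$bias[rows]
    D <- cm_dense(mat, ch)
    # raw counts and the mean raw count at every bin distance
    Draw <- D * (bb %o% bb)
    m_d <- vapply(0:(n - 1L), function(d) {
      ii <- seq_len(n - d)
      mean(Draw[cbind(ii, ii + d)], na.rm = TRUE)
    }, numeric(1))
    m_d[!is.finite(m_d)] <- 0
    # structure-only balancing factors of the expected profile matrix
    edge <- .structure_balance(m_d, u)
    bstar <- bb / edge
    # stratum probabilities re-estimated with the corrected bias
    strat <- decay$strata
    kk <- findInterval(seq(d_lo, min(d_hi, n - 1L)), strat$d_lo)
    count_s <- numeric(nrow(strat)); mass_s <- numeric(nrow(strat))
    for (d in seq(d_lo, min(d_hi, n - 1L))) {
      ii <- seq_len(n - d)
      keep <- u[ii] & u[ii + d]
      if (!any(keep)) next
      s <- kk[d - d_lo + 1L]
      count_s[s] <- count_s[s] + sum(Draw[cbind(ii[keep], ii[keep] + d)])
      mass_s[s] <- mass_s[s] + sum(bstar[ii[keep]] * bstar[ii[keep] + d])
    }
    lam_s <- pava_nonincreasing(ifelse(mass_s > 0, count_s / mass_s, 0), mass_s)
    for (d in seq(d_lo, min(d_hi, n - 1L))) {
      ii <- seq_len(n - d)
      keep <- u[ii] & u[ii + d]
      if (!any(keep)) next
      ii <- ii[keep]
      vals <- D[cbind(ii, ii + d)]
      bp <- bstar[ii] * bstar[ii + d]
      k <- round(Draw[cbind(ii, ii + d)])
      pd <- pmin(lam_s[kk[d - d_lo + 1L]] * bp / N, 1)
      p <- stats::pbinom(k, N, pd, lower.tail = FALSE) +
        0.5 * stats::dbinom(k, N, pd)
      acc[[length(acc) + 1L]] <- list(ch = ch, ii = ii, d = d, vals = vals, p = p)
    }
  }
  if (length(acc) == 0L) stop("no bin pairs in the requested distance range")
  chrom_v <- unlist(lapply(acc, function(a) rep(a$ch, length(a$ii))), use.names = FALSE)
  i_v <- unlist(lapply(acc, `[[`, "ii"), use.names = FALSE)
  d_v <- unlist(lapply(acc, function(a) rep(a$d, length(a$ii))), use.names = FALSE)
  k_v <- unlist(lapply(acc, `[[`, "vals"), use.names = FALSE)
  p_v <- unlist(lapply(acc, `[[`, "p"), use.names = FALSE)
  q_v <- stats::p.adjust(p_v, method = "BH")
  sig <- which(q_v < q_cutoff)
  chrom_starts <- vapply(cm_chroms(mat), function(ch)
    mat$bins$start[cm_chrom_rows(mat, ch)[1]], numeric(1))
  cs <- chrom_starts[chrom_v[sig]]
  out <- data.frame(
    chrom = chrom_v[sig], bin1 = i_v[sig], bin2 = i_v[sig] + d_v[sig],
    start1 = cs + (i_v[sig] - 1) * res, end1 = cs + i_v[sig] * res,
    start2 = cs + (i_v[sig] + d_v[sig] - 1) * res,
    end2 = cs + (i_v[sig] + d_v[sig]) * res,
    distance = d_v[sig] * res,
    count = k_v[sig], p = p_v[sig], q = q_v[sig], stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$bin1, out$bin2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tests") <- length(p_v)
  if (return_pvalues) attr(out, "pvalues") <- p_v
  out
}

# Balancing factors of the structure-only expected matrix M[i,j] =
# m_d[|i-j|+1], restricted to unmasked bins; geometric mean 1.
.structure_balance <- function(m_d, u, max_iter = 100, tol = 1e-4) {
  n <- length(u)
  keep <- which(u)
  M <- matrix(0, length(keep), length(keep))
  idx <- abs(outer(keep, keep, `-`)) + 1L
  M[] <- m_d[idx]
  e <- rep(1, length(keep))
  for (it in seq_len(max_iter)) {
    m <- rowSums(M)
    mm <- mean(m)
    if (mm == 0) break
    s <- m / mm
    if (max(abs(s - 1)) < tol) break
    M <- M / (s %o% s)
    e <- e * s
  }
  out <- rep(1, n)
  out[keep] <- e / exp(mean(log(e)))
  out
}

#' Build the prioritized promoter/enhancer/insulator element sets
#'
#' Sequential construction: promoters are TSS +/- 2 kb windows of expressed
#' genes; enhancers are the top-ranked H3K27ac peaks lying more than 2 kb
#' from any annotated TSS (expressed or not); insulators are the top-ranked
#' CTCF peaks overlapping neither promoters nor enhancers.
#'
#' @param genes gene table (all annotated genes).
#' @param expressed logical vector marking expressed genes (see
#'   \code{\link{call_expressed}}).
#' @param h3k27ac_peaks,ctcf_peaks scored peak data.frames.
#' @param top_n_enhancer,top_n_ctcf score-rank caps (defaults 25000 / 50000;
#'   all peaks are used when fewer are available).
#' @param promoter_halfwidth bp around the TSS (default 2000).
#' @param tss_exclusion minimum distance (bp) of an enhancer peak from any
#'   TSS (default 2000, strict).
#' @return object of class \code{reg_set}: list with \code{promoters},
#'   \code{enhancers}, \code{insulators} interval data.frames.
#' @export
build_regulatory_sets <- function(genes, expressed, h3k27ac_peaks, ctcf_peaks,
                                  top_n_enhancer = 25000, top_n_ctcf = 50000,
                                  promoter_halfwidth = 2000,
                                  tss_exclusion = 2000) {
  promoters <- gene_promoters(genes[expressed, , drop = FALSE],
                              halfwidth = promoter_halfwidth)
  rank_top <- function(peaks, top_n) {
    if (nrow(peaks) == 0L) return(peaks)
    score <- if ("score" %in% names(peaks)) peaks$score else rep(0, nrow(peaks))
    o <- order(-score, peaks$chrom, peaks$start)
    peaks[o[seq_len(min(top_n, nrow(peaks)))], , drop = FALSE]
  }
  enh <- rank_top(h3k27ac_peaks, top_n_enhancer)
  if (nrow(enh) > 0L) {
    tss <- data.frame(chrom = genes$chrom, start = genes$tss, end = genes$tss + 1)
    dist <- distance_to_nearest(enh, tss)
    enh <- enh[is.na(dist) | dist > tss_exclusion, , drop = FALSE]
  }
  ins <- rank_top(ctcf_peaks, top_n_ctcf)
  if (nrow(ins) > 0L) {
    ins <- ins[!overlaps_any(ins, promoters) & !overlaps_any(ins, enh), ,
               drop = FALSE]
  }
  rownames(promoters) <- rownames(enh) <- rownames(ins) <- NULL
  structure(list(promoters = promoters, enhancers = enh, insulators = ins),
            class = "reg_set")
}

# Sequential anchor label: P beats E beats I beats O.
.anchor_labels <- function(anchors, reg_set) {
  lab <- rep("O", nrow(anchors))
  lab[overlaps_any(anchors, reg_set$insulators)] <- "I"
  lab[overlaps_any(anchors, reg_set$enhancers)] <- "E"
  lab[overlaps_any(anchors, reg_set$promoters)] <- "P"
  lab
}

# Canonical unordered category string, ordered P < E < I < O.
.category <- function(l1, l2) {
  ord <- c(P = 1, E = 2, I = 3, O = 4)
  swap <- ord[l2] < ord[l1]
  paste0(ifelse(swap, l2, l1), ifelse(swap, l1, l2))
}

#' Annotate loop anchors with regulatory element classes
#'
#' Each anchor (full fixed-width bin; >= 1 bp overlap) is labelled \code{P}
#' when it overlaps any promoter, else \code{E} for enhancer, else \code{I}
#' for insulator, else \code{O}. The loop category is the unordered label
#' pair (canonical order P, E, I, O), and the category ranking table counts
#' categories in decreasing frequency with lexicographic tie-breaking.
#'
#' @param loops loop data.frame from \code{\link{call_significant_loops}}.
#' @param reg_set a \code{reg_set}.
#' @return the loops with \code{anchor1_label}, \code{anchor2_label},
#'   \code{category}; the ranking table is the \code{"ranking"} attribute.
#' @export
annotate_anchors <- function(loops, reg_set) {
  a1 <- data.frame(chrom = loops$chrom, start = loops$start1, end = loops$end1)
  a2 <- data.frame(chrom = loops$chrom, start = loops$start2, end = loops$end2)
  loops$anchor1_label <- .anchor_labels(a1, reg_set)
  loops$anchor2_label <- .anchor_labels(a2, reg_set)
  loops$category <- if (nrow(loops) > 0L)
    .category(loops$anchor1_label, loops$anchor2_label) else character(0)
  tab <- table(loops$category)
  rank_df <- data.frame(category = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  rank_df <- rank_df[order(-rank_df$count, rank_df$category), , drop = FALSE]
  rownames(rank_df) <- NULL
  attr(loops, "ranking") <- rank_df
  loops
}

#' Top-N most frequent loop categories
#' @param annotated_loops output of \code{\link{annotate_anchors}}.
#' @param n number of categories (default 20).
#' @return ranking data.frame.
#' @export
top_categories <- function(annotated_loops, n = 20) {
  utils::head(attr(annotated_loops, "ranking"), n)
}

#' Loop-fate fractions per regulatory element class
#'
#' For each element class, every element is assigned to exactly one fate:
#' looped to an enhancer, to an insulator, to another element of its own
#' class, to an unmarked region (O), or not looped at all. Elements
#' participating in several loops are assigned by partner priority: the
#' opposite regulatory partner first (promoters: E > I > P > O; enhancers:
#' P > I > E > O; insulators: P > E > I > O). Fractions sum to 1 per class.
#'
#' @param reg_set a \code{reg_set}.
#' @param annotated_loops loops with anchor labels.
#' @return data.frame: class, fate, count, fraction.
#' @export
loop_fate_fractions <- function(reg_set, annotated_loops) {
  priorities <- list(promoters = c("E", "I", "P", "O"),
                     enhancers = c("P", "I", "E", "O"),
                     insulators = c("P", "E", "I", "O"))
  a1 <- data.frame(chrom = annotated_loops$chrom,
                   start = annotated_loops$start1, end = annotated_loops$end1)
  a2 <- data.frame(chrom = annotated_loops$chrom,
                   start = annotated_loops$start2, end = annotated_loops$end2)
  out <- list()
  for (cls in names(priorities)) {
    elems <- reg_set[[cls]]
    if (nrow(elems) == 0L) next
    h1 <- overlap_pairs(elems, a1)
    h2 <- overlap_pairs(elems, a2)
    partners <- rbind(
      data.frame(elem = h1$query,
                 partner = annotated_loops$anchor2_label[h1$subject]),
      data.frame(elem = h2$query,
                 partner = annotated_loops$anchor1_label[h2$subject]))
    fate <- rep("not_looped", nrow(elems))
    if (nrow(partners) > 0L) {
      pr <- priorities[[cls]]
      best <- tapply(match(partners$partner, pr), partners$elem, min)
      fate[as.integer(names(best))] <- paste0("loops_to_", pr[best])
    }
    lev <- c(paste0("loops_to_", priorities[[cls]]), "not_looped")
    tab <- table(factor(fate, levels = lev))
    out[[cls]] <- data.frame(class = cls, fate = names(tab),
                             count = as.integer(tab),
                             fraction = as.integer(tab) / nrow(elems),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Shuffled-anchor empirical null for regulatory element overlap
#'
#' The observed statistic is, per element type, the number of distinct
#' elements on the chosen chromosome overlapped by the real loop anchors.
#' Each of \code{n} shuffles places the same number of non-overlapping
#' fixed-width artificial anchors uniformly on that chromosome and recounts;
#' the add-one empirical p-value is reported per element type.
#'
#' @param loops loop data.frame.
#' @param reg_set a \code{reg_set}.
#' @param chrom chromosome to shuffle on (default the first in \code{loops}).
#' @param chrom_length chromosome length in bp.
#' @param n number of shuffles (default 100).
#' @param anchor_size artificial anchor width in bp (default 10000).
#' @param seed integer seed.
#' @return data.frame: element type, observed count, empirical p.
#' @export
shuffle_anchor_null <- function(loops, reg_set, chrom = NULL, chrom_length,
                                n = 100, anchor_size = 10000, seed = 1) {
  if (is.null(chrom)) chrom <- loops$chrom[1]
  sel <- loops$chrom == chrom
  if (!any(sel)) stop("no loops on chromosome ", chrom)
  anchors <- unique(rbind(
    data.frame(start = loops$start1[sel], end = loops$end1[sel]),
    data.frame(start = loops$start2[sel], end = loops$end2[sel])))
  anchors <- data.frame(chrom = chrom, anchors)
  n_anchor <- nrow(anchors)
  types <- c("promoters", "enhancers", "insulators")
  observed <- vapply(types, function(tp) {
    el <- reg_set[[tp]]
    el <- el[el$chrom == chrom, , drop = FALSE]
    sum(overlaps_any(el, anchors))
  }, numeric(1))
  n_slots <- floor(chrom_length / anchor_size)
  if (n_slots < n_anchor) stop("chromosome too short for the anchor count")
  nulls <- matrix(0, n, length(types), dimnames = list(NULL, types))
  for (s in seq_len(n)) {
    set.seed(substream_seed(seed, "shuffle_anchor_null", s))
    slots <- sample.int(n_slots, n_anchor) - 1L
    art <- data.frame(chrom = chrom, start = slots * anchor_size,
                      end = slots * anchor_size + anchor_size)
    nulls[s, ] <- vapply(types, function(tp) {
      el <- reg_set[[tp]]
      el <- el[el$chrom == chrom, , drop = FALSE]
      sum(overlaps_any(el, art))
    }, numeric(1))
  }
  data.frame(type = types, observed = observed,
             p = vapply(types, function(tp) empirical_pvalue(observed[tp], nulls[, tp]),
                        numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Loop identity key for cross-line matching: exact anchor-bin equality.
loop_keys <- function(loops) {
  if (nrow(loops) == 0L) return(character(0))
  sprintf("%s:%d-%d", loops$chrom, as.integer(loops$start1), as.integer(loops$start2))
}

#' Classify enhancer-promoter loops by cell-line specificity
#'
#' Enhancer-promoter (E-P) loops are loops whose anchor categories are
#' \{P, E\}. Loops are matched across lines by exact anchor-bin equality.
#' Common: present in all three lines' E-P sets; normal-specific: present in
#' the normal line and absent from both cancer lines; cancer-specific:
#' present in both cancer lines and absent from the normal line. A loop in
#' the normal line and exactly one cancer line carries no specificity label.
#'
#' @param loops_by_line named list of three annotated loop data.frames; the
#'   first element is the normal line.
#' @return data.frame: loop key, anchor coordinates, per-line presence, and
#'   \code{specificity} in \{common, normal_specific, cancer_specific,
#'   unlabeled\}.
#' @export
classify_ep_loops <- function(loops_by_line) {
  stopifnot(length(loops_by_line) == 3L)
  nms <- names(loops_by_line)
  if (is.null(nms)) nms <- c("normal", "cancer1", "cancer2")
  ep <- lapply(loops_by_line, function(l) l[l$category == "PE", , drop = FALSE])
  keys <- lapply(ep, loop_keys)
  all_keys <- unique(unlist(keys, use.names = FALSE))
  if (length(all_keys) == 0L) {
    return(data.frame(key = character(0), specificity = character(0)))
  }
  pres <- vapply(keys, function(k) all_keys %in% k, logical(length(all_keys)))
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = 1)
  spec <- rep("unlabeled", length(all_keys))
  spec[pres[, 1] & pres[, 2] & pres[, 3]] <- "common"
  spec[pres[, 1] & !pres[, 2] & !pres[, 3]] <- "normal_specific"
  spec[!pres[, 1] & pres[, 2] & pres[, 3]] <- "cancer_specific"
  # anchor coordinates from whichever line carries the loop
  first_line <- apply(pres, 1, which.max)
  coords <- do.call(rbind, lapply(seq_along(all_keys), function(r) {
    l <- ep[[first_line[r]]]
    l[match(all_keys[r], loop_keys(l)),
      c("chrom", "start1", "end1", "start2", "end2")]
  }))
  out <- data.frame(key = all_keys, coords,
                    stats::setNames(as.data.frame(pres), paste0("in_", nms)),
                    specificity = spec, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fisher exact test for differential loop contact frequency
#'
#' For each loop, the 2x2 table \code{[[k_case, N_case - k_case], [k_control,
#' N_control - k_control]]} is tested two-sided, where k are raw loop counts
#' and N the total in-range intra-chromosomal contact sums per line; p-values
#' are BH-adjusted across the tested loops.
#'
#' @param k_case,k_control raw loop counts (vectors, aligned).
#' @param n_case,n_control scalar total contact counts per line.
#' @return data.frame with \code{odds_ratio}, \code{p}, \code{adj_p}.
#' @export
differential_loop_test <- function(k_case, n_case, k_control, n_control) {
  if (n_case <= 0 || n_control <= 0) stop("total contact counts must be positive")
  stopifnot(length(k_case) == length(k_control))
  p <- vapply(seq_along(k_case), function(r) {
    tab <- matrix(c(k_case[r], n_case - k_case[r],
                    k_control[r], n_control - k_control[r]), 2, byrow = TRUE)
    stats::fisher.test(round(tab))$p.value
  }, numeric(1))
  or <- ((k_case + 0.5) / (n_case - k_case + 0.5)) /
    ((k_control + 0.5) / (n_control - k_control + 0.5))
  data.frame(odds_ratio = or, p = p, adj_p = stats::p.adjust(p, method = "BH"))
}

#' Fraction of looped enhancers bound by a transcription factor
#'
#' Among the distinct enhancers lying at E-labelled anchors of the supplied
#' enhancer-promoter loops, the fraction overlapping at least one TF peak is
#' reported, together with the target genes (genes whose promoter window
#' overlaps the partner anchor of a bound enhancer). When \code{ndrs} is
#' supplied the enhancer set is first restricted to enhancers containing a
#' nucleosome-depleted region.
#'
#' @param annotated_loops annotated loops of one line, restricted by the
#'   caller to the loop class of interest (e.g. cancer-specific E-P loops).
#' @param reg_set the line's \code{reg_set}.
#' @param tf_peaks TF ChIP-seq peak data.frame.
#' @param genes gene table (for target-gene lookup).
#' @param ndrs optional NDR interval data.frame.
#' @return list with \code{fraction}, \code{n_bound}, \code{n_enhancers},
#'   and \code{target_genes}.
#' @export
tf_bound_looped_enhancers <- function(annotated_loops, reg_set, tf_peaks,
                                      genes = NULL, ndrs = NULL) {
  lp <- annotated_loops[annotated_loops$category == "PE", , drop = FALSE]
  a1 <- data.frame(chrom = lp$chrom, start = lp$start1, end = lp$end1)
  a2 <- data.frame(chrom = lp$chrom, start = lp$start2, end = lp$end2)
  enh <- reg_set$enhancers
  if (!is.null(ndrs) && nrow(enh) > 0L) {
    enh <- enh[overlaps_any(enh, ndrs), , drop = FALSE]
  }
  if (nrow(enh) == 0L || nrow(lp) == 0L) {
    return(list(fraction = 0, n_bound = 0L, n_enhancers = 0L,
                target_genes = character(0)))
  }
  h1 <- overlap_pairs(enh, a1)  # enhancer at anchor1 (E side when label E)
  h1 <- h1[lp$anchor1_label[h1$subject] == "E", , drop = FALSE]
  h2 <- overlap_pairs(enh, a2)
  h2 <- h2[lp$anchor2_label[h2$subject] == "E", , drop = FALSE]
  looped_enh <- sort(unique(c(h1$query, h2$query)))
  if (length(looped_enh) == 0L) {
    return(list(fraction = 0, n_bound = 0L, n_enhancers = 0L,
                target_genes = character(0)))
  }
  bound <- looped_enh[overlaps_any(enh[looped_enh, , drop = FALSE], tf_peaks)]
  target_genes <- character(0)
  if (!is.null(genes) && length(bound) > 0L) {
    prom <- gene_promoters(genes)
    partner <- rbind(
      data.frame(anchor = h2$subject, enh = h2$query,
                 side = rep(1L, nrow(h2))),   # enh at a2 -> partner is a1
      data.frame(anchor = h1$subject, enh = h1$query,
                 side = rep(2L, nrow(h1))))   # enh at a1 -> partner is a2
    partner <- partner[partner$enh %in% bound, , drop = FALSE]
    if (nrow(partner) > 0L) {
      panch <- data.frame(
        chrom = lp$chrom[partner$anchor],
        start = ifelse(partner$side == 1L, lp$start1[partner$anchor],
                       lp$start2[partner$anchor]),
        end = ifelse(partner$side == 1L, lp$end1[partner$anchor],
                     lp$end2[partner$anchor]))
      hp <- overlap_pairs(panch, prom)
      target_genes <- sort(unique(prom$name[hp$subject]))
    }
  }
  list(fraction = length(bound) / length(looped_enh),
       n_bound = length(bound), n_enhancers = length(looped_enh),
       target_genes = target_genes)
}

#' Look up raw contact counts for loops
#' @param loops loop data.frame with \code{chrom}, \code{bin1}, \code{bin2}.
#' @param raw_mat raw \code{hic_matrix} at the loop resolution.
#' @return numeric vector of raw counts (0 when absent).
#' @export
loop_raw_counts <- function(loops, raw_mat) {
  out <- numeric(nrow(loops))
  for (ch in unique(loops$chrom)) {
    rows <- cm_chrom_rows(raw_mat, ch)
    D <- cm_dense(raw_mat, ch)
    sel <- which(loops$chrom == ch)
    out[sel] <- D[cbind(loops$bin1[sel], loops$bin2[sel])]
  }
  out
}

# Total in-range intra-chromosomal contact sum of a matrix (differential-test
# denominator).
in_range_total <- function(mat, range = c(5e4, 1e7)) {
  res <- mat$resolution
  d_lo <- ceiling(range[1] / res); d_hi <- floor(range[2] / res)
  tot <- 0
  for (ch in cm_chroms(mat)) {
    rows <- cm_chrom_rows(mat, ch)
    sel <- mat$i >= rows[1] & mat$i <= rows[length(rows)]
    d <- mat$j[sel] - mat$i[sel]
    tot <- tot + sum(mat$x[sel][d >= d_lo & d <= d_hi])
  }
  tot
}
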