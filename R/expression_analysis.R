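# Expression normalization, expressed-gene calling, differential expression,
# and gene-set fold-change comparisons.

#' RPKM normalization
#'
#' \code{RPKM = counts / (gene_length/1e3) / (total_mapped/1e6)}. Linear in
#' counts.
#'
#' @param counts read counts (vector or matrix, genes x replicates).
#' @param gene_length_bp gene length(s) in bp, > 0.
#' @param total_mapped total mapped reads per replicate, > 0.
#' @return RPKM values with the shape of \code{counts}.
#' @export
rpkm <- function(counts, gene_length_bp, total_mapped) {
  if (any(gene_length_bp <= 0)) stop("gene_length must be positive")
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  if (is.matrix(counts)) {
    sweep(counts / (gene_length_bp / 1e3), 2, total_mapped / 1e6, `/`)
  } else {
    counts / (gene_length_bp / 1e3) / (total_mapped / 1e6)
  }
}

#' Call actively expressed genes
#'
#' A gene is expressed when its mean over replicates of \code{log2(RPKM + 1)}
#' is strictly greater than \code{threshold} (default 1.5).
#'
#' @param rpkm_mat RPKM matrix (genes x replicates) or vector.
#' @param threshold mean log2(RPKM+1) cutoff (default 1.5; strict).
#' @return logical vector (one per gene).
#' @export
call_expressed <- function(rpkm_mat, threshold = 1.5) {
  m <- as.matrix(rpkm_mat)
  rowMeans(log2(m + 1)) > threshold
}

#' Differential expression between two conditions
#'
#' Fold change is computed on condition means with a pseudocount,
#' \code{FC = (mean RPKM_case + 1) / (mean RPKM_control + 1)}, which keeps
#' fold changes finite for genes silent in one condition. The p-value is a
#' two-sided t test on \code{log2(RPKM + 1)} across replicates, BH-adjusted
#' over genes. Up-regulated: \code{FC > fc_cutoff} and \code{adj_p < alpha}
#' (both strict); down-regulated symmetrically (\code{FC < 1/fc_cutoff}).
#'
#' @param rpkm_case,rpkm_control RPKM matrices (genes x replicates,
#'   row-aligned).
#' @param fc_cutoff fold-change cutoff (default 2).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return data.frame with \code{fc}, \code{log2fc}, \code{p}, \code{adj_p},
#'   \code{up}, \code{down}. With fewer than 2 replicates per condition the
#'   p-values are NA and only fold changes are reported.
#' @export
differential_expression <- function(rpkm_case, rpkm_control, fc_cutoff = 2,
                                    alpha = 0.05) {
  rpkm_case <- as.matrix(rpkm_case); rpkm_control <- as.matrix(rpkm_control)
  stopifnot(nrow(rpkm_case) == nrow(rpkm_control))
  mc <- rowMeans(rpkm_case); mn <- rowMeans(rpkm_control)
  fc <- (mc + 1) / (mn + 1)
  p <- rep(NA_real_, nrow(rpkm_case))
  if (ncol(rpkm_case) >= 2L && ncol(rpkm_control) >= 2L) {
    lc <- log2(rpkm_case + 1); ln <- log2(rpkm_control + 1)
    for (g in seq_len(nrow(lc))) {
      p[g] <- tryCatch(stats::t.test(lc[g, ], ln[g, ])$p.value,
                       error = function(e) 1)
    }
  }
  adj_p <- stats::p.adjust(p, method = "BH")
  data.frame(fc = fc, log2fc = log2(fc), p = p, adj_p = adj_p,
             up = !is.na(adj_p) & fc > fc_cutoff & adj_p < alpha,
             down = !is.na(adj_p) & fc < 1 / fc_cutoff & adj_p < alpha)
}

#' Compare log2 fold-change distributions between gene sets
#'
#' Two-sided rank-sum tests (exact permutation enumeration for small sets) on
#' the log2 fold changes of each pair of gene sets, BH-adjusted across the
#' comparisons in the report.
#'
#' @param fold_changes named numeric vector of per-gene log2 fold changes.
#' @param gene_sets named list of gene-id vectors (>= 2 genes each;
#'   disjointness is not required).
#' @return data.frame with set pair, sizes, medians, p and adjusted p.
#' @export
compare_gene_sets <- function(fold_changes, gene_sets) {
  vals <- lapply(gene_sets, function(g) {
    v <- fold_changes[intersect(g, names(fold_changes))]
    v[!is.na(v)]
  })
  vals <- vals[lengths(vals) >= 2L]
  if (length(vals) < 2L) stop("need at least two gene sets with >= 2 genes")
  pairs <- utils::combn(names(vals), 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- vals[[pairs[1, k]]]; b <- vals[[pairs[2, k]]]
    data.frame(set1 = pairs[1, k], set2 = pairs[2, k],
               n1 = length(a), n2 = length(b),
               median1 = stats::median(a), median2 = stats::median(b),
               p = ranksum_test(a, b)$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out
}
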