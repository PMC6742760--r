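# Synthetic multi-cell-line 3D-epigenome dataset with recorded ground truth:
# distance-decaying contact matrices with planted TAD blocks, loop-pair
# enrichments and per-bin bias; histone-mark peak sets concentrated in the
# TADs of their state; CTCF at boundaries and anchors; NDRs nested in
# H3K27ac peaks; genes with planted condition effects at cancer-specific
# loop anchors. Fully deterministic under (seed, config).

#' Simulation configuration
#'
#' Defaults describe a miniature three-line design (one normal, two cancer
#' lines sharing a cancer TAD partition and cancer-specific loops): two 20 Mb
#' chromosomes binned at 10 kb (fine, loops) and 40 kb (coarse, TADs),
#' power-law distance decay, multiplicative within-TAD and anchor-pair
#' enrichments, per-bin log-normal bias, and Poisson counts.
#'
#' @param n_chroms number of chromosomes (default 2).
#' @param chrom_length chromosome length in bp (default 20 Mb).
#' @param fine_resolution loop-calling bin size (default 10 kb).
#' @param coarse_resolution TAD-calling bin size (default 40 kb; must be an
#'   integer multiple of the fine resolution).
#' @param decay_exponent power-law exponent alpha > 0 of the expected count
#'   \code{C * (d+1)^-alpha} at bin distance d (default 1).
#' @param tad_boost multiplicative enrichment for bin pairs inside the same
#'   planted TAD (default 3; > 1).
#' @param loop_boost multiplicative enrichment at planted anchor pairs,
#'   applied at exactly the anchor bin pair (default 5; > 1).
#' @param depth target total contact count per chromosome (default 4e7,
#'   deep enough that fine-scale bin pairs in the loop-calling range are
#'   rarely empty).
#' @param bias_sd standard deviation of the per-bin log-normal bias on the
#'   natural-log scale (default 0.3).
#' @param conditions condition names; the first is the normal line, the rest
#'   cancer lines (default normal, cancerA, cancerB).
#' @param n_tads_per_chrom planted TADs per chromosome in the normal
#'   partition (default 25).
#' @param n_split_tads how many normal TADs split into two cancer TADs
#'   (default 5 per chromosome).
#' @param n_loops_per_class planted loops per chromosome for each specificity
#'   class (common / normal_specific / cancer_specific; default 12).
#' @param n_genes_per_chrom background genes per chromosome (default 400).
#' @param expression_effect fold-change planted on genes whose promoters
#'   anchor cancer-specific loops (default 4).
#' @param expression_sd replicate noise sd of log2(RPKM+1) (default 0.25).
#' @param n_replicates RNA replicates per condition (default 3).
#' @param tf_bound_fraction fraction of cancer-specific looped enhancers
#'   covered by a TF peak (default 0.3).
#' @param seed root seed; every stage derives a named substream from it.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 2e7,
                       fine_resolution = 1e4, coarse_resolution = 4e4,
                       decay_exponent = 1, tad_boost = 3, loop_boost = 5,
                       depth = 4e7, bias_sd = 0.3,
                       conditions = c("normal", "cancerA", "cancerB"),
                       n_tads_per_chrom = 25, n_split_tads = 5,
                       n_loops_per_class = 12, n_genes_per_chrom = 400,
                       expression_effect = 4, expression_sd = 0.25,
                       n_replicates = 3, tf_bound_fraction = 0.3, seed = 1) {
  stopifnot(coarse_resolution %% fine_resolution == 0,
            coarse_resolution > fine_resolution,
            decay_exponent > 0, tad_boost >= 1, loop_boost >= 1,
            length(conditions) >= 1)
  cfg <- list(n_chroms = n_chroms, chrom_length = chrom_length,
              fine_resolution = fine_resolution,
              coarse_resolution = coarse_resolution,
              decay_exponent = decay_exponent, tad_boost = tad_boost,
              loop_boost = loop_boost, depth = depth, bias_sd = bias_sd,
              conditions = conditions, n_tads_per_chrom = n_tads_per_chrom,
              n_split_tads = n_split_tads, n_loops_per_class = n_loops_per_class,
              n_genes_per_chrom = n_genes_per_chrom,
              expression_effect = expression_effect,
              expression_sd = expression_sd, n_replicates = n_replicates,
              tf_bound_fraction = tf_bound_fraction, seed = seed)
  cfg$chrom_sizes <- stats::setNames(rep(chrom_length, n_chroms),
                                     paste0("chr", seq_len(n_chroms)))
  class(cfg) <- "sim_config"
  cfg
}

#' Depth giving a target mean diagonal count at a chosen resolution
#'
#' Computes the per-chromosome total contact count at which the expected mean
#' diagonal entry of the matrix coarsened to \code{resolution} equals
#' \code{target} (structure-free decay; boosts increase it slightly).
#'
#' @param config a \code{sim_config}.
#' @param target desired mean diagonal count (e.g. 100).
#' @param resolution resolution of the coarsened matrix (default the coarse
#'   resolution).
#' @return depth value to place in the configuration.
#' @export
depth_for_diagonal <- function(config, target = 100,
                               resolution = config$coarse_resolution) {
  a <- config$decay_exponent
  n <- floor(config$chrom_length / config$fine_resolution)
  f <- resolution / config$fine_resolution
  d <- 0:(n - 1)
  # fraction of pairs at distance d inside one TAD, for TADs tiling the
  # chromosome at the average planted size
  s <- n / config$n_tads_per_chrom
  samefrac <- pmax(0, 1 - d / s)
  boost <- 1 + samefrac * (config$tad_boost - 1)
  mass_unit <- sum((n - d) * (d + 1)^(-a) * boost)   # total mass at C = 1
  # expected coarse diagonal entry at C = 1: fine pairs in the f x f block
  # intersected with the upper triangle (virtually all inside one TAD)
  off <- 0:(f - 1)
  diag_unit <- sum((f - off) * (off + 1)^(-a) * config$tad_boost)
  target / diag_unit * mass_unit
}

# --- ground truth -------------------------------------------------------------

# Partition [0, n_bins) into k segments of >= min_bins coarse bins: each
# segment gets the minimum plus an exponential share of the remainder.
.random_partition <- function(n_bins, k, min_bins) {
  rest <- n_bins - k * min_bins
  if (rest < 0) stop("chromosome too short for the requested TAD count")
  u <- stats::rexp(k)
  extra <- floor(u / sum(u) * rest)
  short <- rest - sum(extra)
  if (short > 0) {
    top <- order(-(u / sum(u) * rest - extra))[seq_len(short)]
    extra[top] <- extra[top] + 1L
  }
  cumsum(min_bins + extra)
}

#' Plant the ground truth for a synthetic dataset
#'
#' Draws, per chromosome: a normal TAD partition; a cancer partition in which
#' a subset of normal TADs is split in two (those parents are the planted
#' normal-specific TADs, their children the cancer-specific TADs, everything
#' else common); per-TAD chromatin states per condition, with a subset of
#' common TADs flipping state between normal and cancer; planted loop anchor
#' pairs per specificity class (each an enhancer-promoter pair); genes with
#' density highest in active TADs; per-condition expression with planted
#' up-regulation of genes whose promoters anchor cancer-specific loops; and
#' the per-bin bias vector.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{ground_truth}.
#' @export
make_ground_truth <- function(config) {
  set.seed(substream_seed(config$seed, "ground_truth"))
  fres <- config$fine_resolution
  cres <- config$coarse_resolution
  fac <- cres %/% fres
  states <- c("H3K36me3", "H3K27me3", "H3K9me3", "other")
  state_prob <- c(0.15, 0.15, 0.12, 0.58)   # each mark's prevalence stays
                                            # below the 25% signal-quantile cut
                                            # with margin for sampling noise
  tads_normal <- list(); tads_cancer <- list(); loops <- list()
  flips <- list()
  for (ci in seq_len(config$n_chroms)) {
    ch <- names(config$chrom_sizes)[ci]
    nb <- as.integer(config$chrom_sizes[[ci]] %/% cres)
    ends <- .random_partition(nb, config$n_tads_per_chrom, min_bins = 8L)
    starts <- c(0L, ends[-length(ends)])
    tn <- data.frame(chrom = ch, start = starts * cres, end = ends * cres,
                     stringsAsFactors = FALSE)
    tn$state_normal <- sample(states, nrow(tn), replace = TRUE, prob = state_prob)
    # split parents: the largest eligible TADs split into two cancer children
    eligible <- which((tn$end - tn$start) / cres >= 16)
    parents <- utils::head(eligible[order(-(tn$end - tn$start)[eligible])],
                           config$n_split_tads)
    tn$split <- seq_len(nrow(tn)) %in% parents
    tc <- list()
    for (r in seq_len(nrow(tn))) {
      if (tn$split[r]) {
        nb_tad <- (tn$end[r] - tn$start[r]) / cres
        cut <- sample(seq(6L, nb_tad - 6L), 1L)
        tc[[length(tc) + 1L]] <- data.frame(
          chrom = ch, start = c(tn$start[r], tn$start[r] + cut * cres),
          end = c(tn$start[r] + cut * cres, tn$end[r]),
          parent = r, class = "cancer_specific", stringsAsFactors = FALSE)
      } else {
        tc[[length(tc) + 1L]] <- data.frame(
          chrom = ch, start = tn$start[r], end = tn$end[r],
          parent = r, class = "common", stringsAsFactors = FALSE)
      }
    }
    tc <- do.call(rbind, tc)
    # cancer states: children of split parents are active more often; common
    # TADs keep the normal state except planted flips
    tc$state_cancer <- tn$state_normal[tc$parent]
    kids <- tc$class == "cancer_specific"
    tc$state_cancer[kids] <- sample(states, sum(kids), replace = TRUE,
                                    prob = c(0.5, 0.15, 0.1, 0.25))
    # planted state flips: balanced across target states so no mark's
    # prevalence among common TADs exceeds the 25% signal-quantile cap the
    # state classifier assumes
    common_idx <- which(tc$class == "common")
    n_flip <- min(4L, length(common_idx))
    flip_rows <- sample(common_idx, n_flip)
    for (k in seq_along(flip_rows)) {
      r <- flip_rows[k]
      targets <- setdiff(states, tc$state_cancer[r])
      tc$state_cancer[r] <- targets[(k - 1L) %% length(targets) + 1L]
    }
    tn$state_cancer <- NA_character_
    tn$state_cancer[tc$parent] <- tc$state_cancer  # last child wins; parents split
    flips[[ch]] <- data.frame(chrom = ch, start = tc$start[flip_rows],
                              end = tc$end[flip_rows],
                              from = tn$state_normal[tc$parent[flip_rows]],
                              to = tc$state_cancer[flip_rows],
                              stringsAsFactors = FALSE)
    tn$chrom_index <- ci; tc$chrom_index <- ci
    tads_normal[[ch]] <- tn; tads_cancer[[ch]] <- tc

    # planted loops: enhancer-promoter anchor pairs at fine bins, distances
    # 60 kb - 2 Mb, anchors kept away from TAD boundaries and from each other
    nfine <- as.integer(config$chrom_sizes[[ci]] %/% fres)
    boundary_fine <- unique(c(ends, starts) * fac)
    used <- integer(0)
    d_max <- min(as.integer(2e6 %/% fres), nfine - 12L)
    draw_pair <- function() {
      for (t in 1:500) {
        d <- sample(seq(6L, d_max), 1L)
        i <- sample.int(nfine - d - 2L, 1L)
        j <- i + d
        cand <- c(i, j)
        if (any(cand %in% used)) next
        if (any(abs(outer(cand, boundary_fine, `-`)) <= 2L)) next
        if (length(used) > 0L && any(abs(outer(cand, used, `-`)) <= 2L)) next
        used <<- c(used, cand)
        return(c(i, j))
      }
      stop("could not place a planted loop pair")
    }
    for (cls in c("common", "normal_specific", "cancer_specific")) {
      for (k in seq_len(config$n_loops_per_class)) {
        pr <- draw_pair()
        # promoter anchor drawn at random between the two ends
        pa <- sample(1:2, 1L)
        loops[[length(loops) + 1L]] <- data.frame(
          chrom = ch, bin1 = pr[1], bin2 = pr[2],
          start1 = (pr[1] - 1L) * fres, start2 = (pr[2] - 1L) * fres,
          promoter_anchor = pa, class = cls, stringsAsFactors = FALSE)
      }
    }
  }
  tads_normal <- do.call(rbind, tads_normal)
  tads_cancer <- do.call(rbind, tads_cancer)
  loops <- if (length(loops) > 0L) do.call(rbind, loops) else
    data.frame(chrom = character(0), bin1 = integer(0), bin2 = integer(0),
               start1 = numeric(0), start2 = numeric(0),
               promoter_anchor = integer(0), class = character(0))
  rownames(tads_normal) <- rownames(tads_cancer) <- rownames(loops) <- NULL
  loops$loop_id <- sprintf("loop_%03d", seq_len(nrow(loops)))
  loops$end1 <- loops$start1 + fres
  loops$end2 <- loops$start2 + fres

  # per-bin bias (fine resolution), geometric mean 1
  bias <- lapply(names(config$chrom_sizes), function(ch) {
    n <- as.integer(config$chrom_sizes[[ch]] %/% fres)
    exp(stats::rnorm(n, 0, config$bias_sd))
  })
  names(bias) <- names(config$chrom_sizes)

  truth <- list(config = config, tads_normal = tads_normal,
                tads_cancer = tads_cancer, loops = loops,
                state_flips = do.call(rbind, flips), bias = bias)
  truth$genes <- .plant_genes(config, truth)
  truth$expression <- .plant_expression(config, truth)
  class(truth) <- "ground_truth"
  truth
}

# Genes: density highest in active TADs; one gene planted at every planted
# promoter anchor; background TSSs kept > 12 kb from enhancer anchors so
# planted enhancers survive the TSS-exclusion rule.
.plant_genes <- function(config, truth) {
  set.seed(substream_seed(config$seed, "genes"))
  fres <- config$fine_resolution
  genes <- list()
  enh_anchor_start <- ifelse(truth$loops$promoter_anchor == 1L,
                             truth$loops$start2, truth$loops$start1)
  prom_anchor_start <- ifelse(truth$loops$promoter_anchor == 1L,
                              truth$loops$start1, truth$loops$start2)
  gid <- 0L
  for (ch in names(config$chrom_sizes)) {
    tn <- truth$tads_normal[truth$tads_normal$chrom == ch, ]
    wts <- c(H3K36me3 = 4, other = 2, H3K27me3 = 1, H3K9me3 = 0.5)
    tad_w <- wts[tn$state_normal] * (tn$end - tn$start)
    enh_ch <- enh_anchor_start[truth$loops$chrom == ch]
    n_bg <- config$n_genes_per_chrom
    tss <- numeric(0)
    while (length(tss) < n_bg) {
      r <- sample.int(nrow(tn), n_bg, replace = TRUE, prob = tad_w)
      pos <- floor(stats::runif(n_bg, tn$start[r] + 2000, tn$end[r] - 2000))
      ok <- vapply(pos, function(p) all(abs(p - (enh_ch + fres / 2)) > 12000),
                   logical(1))
      tss <- c(tss, pos[ok])
    }
    tss <- tss[seq_len(n_bg)]
    genes[[ch]] <- data.frame(
      gene_id = sprintf("gene_%s_%04d", ch, seq_along(tss)),
      chrom = ch, strand = sample(c("+", "-"), length(tss), replace = TRUE),
      tss = sort(tss),
      length = round(stats::runif(length(tss), 1000, 50000)),
      planted_loop = NA_character_, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  # planted promoter-anchor genes, TSS centered in the anchor bin
  pa <- data.frame(
    gene_id = sprintf("gene_loop_%03d", seq_len(nrow(truth$loops))),
    chrom = truth$loops$chrom,
    strand = sample(c("+", "-"), nrow(truth$loops), replace = TRUE),
    tss = prom_anchor_start + fres / 2,
    length = round(stats::runif(nrow(truth$loops), 5000, 30000)),
    planted_loop = truth$loops$loop_id, stringsAsFactors = FALSE)
  out <- rbind(genes, pa)
  out <- out[order(out$chrom, out$tss), ]
  rownames(out) <- NULL
  out
}

# Expression: log2(RPKM+1) baseline by TAD state, loop-promoter genes kept
# clearly expressed; cancer-specific loop-promoter genes up-regulated by the
# planted effect in BOTH cancer conditions; replicate noise N(0, sd).
.plant_expression <- function(config, truth) {
  set.seed(substream_seed(config$seed, "expression"))
  g <- truth$genes
  ng <- nrow(g)
  tn <- truth$tads_normal
  tss <- data.frame(chrom = g$chrom, start = g$tss, end = g$tss + 1)
  hit <- overlap_pairs(tss, tn)
  state <- rep("other", ng)
  state[hit$query] <- tn$state_normal[hit$subject]
  base <- stats::rnorm(ng, mean = c(H3K36me3 = 3.2, other = 1.2,
                                    H3K27me3 = 0.4, H3K9me3 = 0.3)[state],
                       sd = 0.8)
  planted <- !is.na(g$planted_loop)
  base[planted] <- stats::rnorm(sum(planted), 3.2, 0.4)
  up_genes <- planted &
    g$planted_loop %in% truth$loops$loop_id[truth$loops$class == "cancer_specific"]
  cond_mean <- matrix(rep(pmax(base, 0), length(config$conditions)), ncol = length(config$conditions),
                      dimnames = list(g$gene_id, config$conditions))
  cancer_conditions <- config$conditions[-1]
  cond_mean[up_genes, cancer_conditions] <-
    cond_mean[up_genes, cancer_conditions] + log2(config$expression_effect)
  reps <- config$n_replicates
  expr <- list()
  for (cond in config$conditions) {
    m <- matrix(stats::rnorm(ng * reps, mean = cond_mean[, cond],
                             sd = config$expression_sd), ng, reps)
    m <- pmax(2^m - 1, 0)        # back to RPKM
    dimnames(m) <- list(g$gene_id, paste0(cond, "_rep", seq_len(reps)))
    expr[[cond]] <- m
  }
  list(rpkm = do.call(cbind, expr), upregulated = g$gene_id[up_genes],
       tad_state = state)
}

# --- contact matrices ---------------------------------------------------------

#' Simulate a contact matrix for one condition
#'
#' Expected count for a bin pair at distance d bins:
#' \code{lambda = C * (d+1)^-alpha}, times \code{tad_boost} when both bins
#' fall in the same planted TAD of the condition's partition, times
#' \code{loop_boost} at exactly the planted anchor pairs present in the
#' condition. Observed counts are \code{Poisson(b_i * b_j * lambda)} with the
#' planted per-bin bias; C is set so the expected total mass equals the
#' configured depth per chromosome.
#'
#' @param config a \code{sim_config}.
#' @param truth matching \code{\link{make_ground_truth}} output.
#' @param condition condition name (first configured condition = normal).
#' @return raw \code{\link{hic_matrix}} at the fine resolution.
#' @export
simulate_contact_matrix <- function(config, truth, condition) {
  stopifnot(condition %in% config$conditions)
  set.seed(substream_seed(config$seed, paste0("matrix_", condition)))
  fres <- config$fine_resolution
  a <- config$decay_exponent
  is_normal <- condition == config$conditions[1]
  tads <- if (is_normal) truth$tads_normal else truth$tads_cancer
  keep_class <- if (is_normal) c("common", "normal_specific") else
    c("common", "cancer_specific")
  loops <- truth$loops[truth$loops$class %in% keep_class, , drop = FALSE]
  bins <- make_bin_table(config$chrom_sizes, fres)
  ii <- list(); jj <- list(); xx <- list()
  for (ch in names(config$chrom_sizes)) {
    rows <- which(bins$chrom == ch)
    n <- length(rows)
    b <- truth$bias[[ch]]
    td <- tads[tads$chrom == ch, ]
    tad_of <- rep(0L, n)
    for (r in seq_len(nrow(td))) {
      lo <- td$start[r] %/% fres + 1L
      hi <- min(n, td$end[r] %/% fres)
      tad_of[lo:hi] <- r
    }
    lp <- loops[loops$chrom == ch, ]
    # calibrate C so expected total (with boosts and bias ~ 1) matches depth
    d_all <- 0:(n - 1)
    samefrac <- vapply(d_all, function(d) {
      idx <- seq_len(n - d)
      mean(tad_of[idx] > 0 & tad_of[idx] == tad_of[idx + d])
    }, numeric(1))
    mass_unit <- sum((n - d_all) * (d_all + 1)^(-a) *
                       (1 + samefrac * (config$tad_boost - 1)))
    C <- config$depth / mass_unit
    if (C < 1) warning("depth too small: mean diagonal count below 1")
    for (d in d_all) {
      idx <- seq_len(n - d)
      lam <- C * (d + 1)^(-a) *
        ifelse(tad_of[idx] > 0 & tad_of[idx] == tad_of[idx + d],
               config$tad_boost, 1)
      lam <- lam * b[idx] * b[idx + d]
      sel <- lp$bin2 - lp$bin1 == d
      if (any(sel)) lam[lp$bin1[sel]] <- lam[lp$bin1[sel]] * config$loop_boost
      x <- stats::rpois(length(idx), lam)
      nz <- x > 0
      if (any(nz)) {
        ii[[length(ii) + 1L]] <- rows[idx[nz]]
        jj[[length(jj) + 1L]] <- rows[idx[nz] + d]
        xx[[length(xx) + 1L]] <- x[nz]
      }
    }
  }
  hic_matrix(bins, unlist(ii, use.names = FALSE), unlist(jj, use.names = FALSE),
             unlist(xx, use.names = FALSE), fres)
}

# --- annotations --------------------------------------------------------------

# Peaks inside TADs of a given state: one peak per ~15 kb of TAD, >= 12.
.peaks_in_tads <- function(tads, state_col, state, width, score_range) {
  sel <- tads[tads[[state_col]] == state, , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(sel))) {
    k <- max(12L, as.integer((sel$end[r] - sel$start[r]) / 15000))
    pos <- floor(stats::runif(k, sel$start[r], sel$end[r] - width))
    out[[r]] <- data.frame(chrom = sel$chrom[r], start = pos, end = pos + width,
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), score = numeric(0)))
  }
  res <- do.call(rbind, out)
  res$score <- stats::runif(nrow(res), score_range[1], score_range[2])
  res[order(res$chrom, res$start), ]
}

# Binned fold-change-like signal track for one mark.
.signal_track <- function(config, tads, state_col, state) {
  fres <- config$fine_resolution
  out <- list()
  for (ch in names(config$chrom_sizes)) {
    n <- as.integer(config$chrom_sizes[[ch]] %/% fres)
    v <- stats::rnorm(n, 0.5, 0.2)
    td <- tads[tads$chrom == ch & tads[[state_col]] == state, , drop = FALSE]
    for (r in seq_len(nrow(td))) {
      lo <- td$start[r] %/% fres + 1L
      hi <- min(n, td$end[r] %/% fres)
      v[lo:hi] <- stats::rnorm(hi - lo + 1L, 3, 0.3)
    }
    out[[ch]] <- data.frame(chrom = ch, start = (seq_len(n) - 1) * fres,
                            end = seq_len(n) * fres, value = pmax(v, 0),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate the annotation tracks for one condition
#'
#' Emits, for the condition's planted TAD partition and loop set: histone
#' mark peak sets (H3K36me3/H3K27me3/H3K9me3 inside TADs of their state,
#' H3K27ac inside active TADs and at the enhancer anchor of every planted
#' loop present in the condition), binned signal tracks per mark, CTCF peaks
#' at TAD boundaries and loop anchors, NDRs nested inside H3K27ac peaks, TF
#' peaks covering a configured fraction of cancer-specific looped enhancers
#' (cancer conditions only), and the condition's gene/expression table.
#'
#' @param config a \code{sim_config}.
#' @param truth matching ground truth.
#' @param condition condition name.
#' @return list with \code{peaks} (named list per mark), \code{tracks},
#'   \code{ctcf}, \code{ndrs}, \code{tf_peaks}, \code{genes} (gene table with
#'   this condition's RPKM replicate columns).
#' @export
simulate_annotations <- function(config, truth, condition) {
  stopifnot(condition %in% config$conditions)
  set.seed(substream_seed(config$seed, paste0("annot_", condition)))
  fres <- config$fine_resolution
  is_normal <- condition == config$conditions[1]
  tads <- if (is_normal) truth$tads_normal else truth$tads_cancer
  state_col <- if (is_normal) "state_normal" else "state_cancer"
  keep_class <- if (is_normal) c("common", "normal_specific") else
    c("common", "cancer_specific")
  loops <- truth$loops[truth$loops$class %in% keep_class, , drop = FALSE]

  peaks <- list()
  tracks <- list()
  for (mk in c("H3K36me3", "H3K27me3", "H3K9me3")) {
    peaks[[mk]] <- .peaks_in_tads(tads, state_col, mk, width = 1000,
                                  score_range = c(2, 10))
    tracks[[mk]] <- .signal_track(config, tads, state_col, mk)
  }
  # H3K27ac: background peaks in active TADs + planted enhancer-anchor peaks;
  # background peaks are kept away from ALL planted enhancer-anchor bins so
  # that anchor H3K27ac presence is exactly condition-specific
  k27 <- .peaks_in_tads(tads, state_col, "H3K36me3", width = 2000,
                        score_range = c(1, 6))
  all_enh_start <- ifelse(truth$loops$promoter_anchor == 1L,
                          truth$loops$start2, truth$loops$start1)
  if (nrow(k27) > 0L && nrow(truth$loops) > 0L) {
    anchor_bins <- data.frame(chrom = truth$loops$chrom,
                              start = all_enh_start,
                              end = all_enh_start + fres)
    k27 <- k27[!overlaps_any(k27, anchor_bins), , drop = FALSE]
  }
  enh_start <- ifelse(loops$promoter_anchor == 1L, loops$start2, loops$start1)
  enh_peaks <- data.frame(chrom = loops$chrom,
                          start = enh_start + (fres - 3000) / 2,
                          end = enh_start + (fres + 3000) / 2,
                          score = stats::runif(nrow(loops), 8, 10),
                          stringsAsFactors = FALSE)
  peaks$H3K27ac <- rbind(k27, enh_peaks)
  peaks$H3K27ac <- peaks$H3K27ac[order(peaks$H3K27ac$chrom, peaks$H3K27ac$start), ]
  rownames(peaks$H3K27ac) <- NULL
  tracks$H3K27ac <- .signal_track(config, tads, state_col, "H3K36me3")

  # CTCF at TAD boundaries and loop anchors, plus background
  bdry <- unique(data.frame(chrom = rep(tads$chrom, 2),
                            pos = c(tads$start, tads$end)))
  ctcf <- data.frame(chrom = bdry$chrom, start = pmax(0, bdry$pos - 200),
                     end = bdry$pos + 200,
                     score = stats::runif(nrow(bdry), 6, 10))
  anc <- data.frame(chrom = rep(loops$chrom, 2),
                    start = c(loops$start1, loops$start2) + fres / 2 - 200)
  ctcf_anc <- data.frame(chrom = anc$chrom, start = anc$start,
                         end = anc$start + 400,
                         score = stats::runif(nrow(anc), 6, 10))
  n_bg <- 50L * config$n_chroms
  bg_ch <- sample(names(config$chrom_sizes), n_bg, replace = TRUE)
  bg_pos <- floor(stats::runif(n_bg, 0, config$chrom_length - 400))
  ctcf_bg <- data.frame(chrom = bg_ch, start = bg_pos, end = bg_pos + 400,
                        score = stats::runif(n_bg, 1, 5))
  ctcf <- rbind(ctcf, ctcf_anc, ctcf_bg)
  ctcf <- ctcf[order(ctcf$chrom, ctcf$start), ]
  rownames(ctcf) <- NULL

  # NDRs nested inside every H3K27ac peak
  mid <- (peaks$H3K27ac$start + peaks$H3K27ac$end) / 2
  ndrs <- data.frame(chrom = peaks$H3K27ac$chrom, start = floor(mid - 75),
                     end = floor(mid + 75), stringsAsFactors = FALSE)

  # TF peaks: the factor binds a configured fraction of ALL active-enhancer
  # peaks in the cancer conditions (placed at the peak centre, NDR-sized), so
  # any enhancer subset recovered downstream is bound at about that rate; in
  # the normal condition the factor is not active and leaves only scattered
  # background binding
  tf <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  if (!is_normal) {
    k27all <- peaks$H3K27ac
    n_bound <- round(config$tf_bound_fraction * nrow(k27all))
    bound <- sort(sample.int(nrow(k27all), n_bound))
    mid27 <- (k27all$start[bound] + k27all$end[bound]) / 2
    tf <- data.frame(chrom = k27all$chrom[bound], start = floor(mid27 - 150),
                     end = floor(mid27 + 150), stringsAsFactors = FALSE)
  }
  n_bg <- 25L * config$n_chroms
  bg_ch <- sample(names(config$chrom_sizes), n_bg, replace = TRUE)
  bg_pos <- floor(stats::runif(n_bg, 0, config$chrom_length - 300))
  tf <- rbind(tf, data.frame(chrom = bg_ch, start = bg_pos, end = bg_pos + 300))
  tf <- tf[order(tf$chrom, tf$start), ]
  rownames(tf) <- NULL

  expr_cols <- paste0(condition, "_rep", seq_len(config$n_replicates))
  genes <- cbind(truth$genes, as.data.frame(truth$expression$rpkm[, expr_cols]))
  attr(genes, "expr_cols") <- expr_cols

  list(peaks = peaks, tracks = tracks, ctcf = ctcf, ndrs = ndrs,
       tf_peaks = tf, genes = genes)
}

#' Simulate a complete multi-condition dataset
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{hic_dataset}: \code{config}, \code{truth},
#'   per-condition raw fine-resolution \code{matrices} and
#'   \code{annotations}, and the full gene/expression table.
#' @export
simulate_dataset <- function(config = sim_config()) {
  truth <- make_ground_truth(config)
  matrices <- lapply(config$conditions, function(cond)
    simulate_contact_matrix(config, truth, cond))
  annotations <- lapply(config$conditions, function(cond)
    simulate_annotations(config, truth, cond))
  names(matrices) <- names(annotations) <- config$conditions
  genes <- truth$genes
  genes <- cbind(genes, as.data.frame(truth$expression$rpkm))
  attr(genes, "expr_cols") <- colnames(truth$expression$rpkm)
  structure(list(config = config, truth = truth, matrices = matrices,
                 annotations = annotations, genes = genes),
            class = "hic_dataset")
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' Per condition: triplet matrix + bin BED, one BED per histone mark, CTCF,
#' NDR and TF peak BEDs; one shared gene table TSV with all expression
#' columns; the ground truth as JSON.
#'
#' @param dataset a \code{hic_dataset}.
#' @param outdir output directory (created if needed).
#' @return \code{outdir}, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (cond in dataset$config$conditions) {
    write_contact_matrix(dataset$matrices[[cond]],
                         file.path(outdir, paste0(cond, "_matrix.tsv")),
                         file.path(outdir, paste0(cond, "_bins.bed")))
    ann <- dataset$annotations[[cond]]
    for (mk in names(ann$peaks)) {
      pk <- ann$peaks[[mk]]
      pk$name <- sprintf("%s_%d", mk, seq_len(nrow(pk)))
      write_bed(pk[, c("chrom", "start", "end", "name", "score")],
                file.path(outdir, sprintf("%s_%s_peaks.bed", cond, mk)))
      write_tsv(ann$tracks[[mk]],
                file.path(outdir, sprintf("%s_%s_track.tsv", cond, mk)))
    }
    ct <- ann$ctcf; ct$name <- sprintf("CTCF_%d", seq_len(nrow(ct)))
    write_bed(ct[, c("chrom", "start", "end", "name", "score")],
              file.path(outdir, paste0(cond, "_CTCF_peaks.bed")))
    write_bed(ann$ndrs, file.path(outdir, paste0(cond, "_NDR.bed")))
    write_bed(ann$tf_peaks, file.path(outdir, paste0(cond, "_TF_peaks.bed")))
  }
  write_gene_table(dataset$genes, file.path(outdir, "genes.tsv"))
  truth <- dataset$truth
  jsonlite::write_json(
    list(tads_normal = truth$tads_normal, tads_cancer = truth$tads_cancer,
         loops = truth$loops, state_flips = truth$state_flips,
         upregulated = truth$expression$upregulated,
         chrom_sizes = as.list(truth$config$chrom_sizes)),
    file.path(outdir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
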