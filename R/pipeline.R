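# Orchestration of the full per-cell-line analysis and the three-way
# comparison: normalize -> TADs -> states -> loops -> anchors -> specific
# E-P loops -> expression links. Deterministic under a single root seed.

#' Pipeline parameters
#'
#' All thresholds of the analysis with their default values; every one can
#' be overridden.
#'
#' @param fine_resolution loop-calling resolution (10 kb).
#' @param coarse_resolution TAD-calling resolution (40 kb).
#' @param q_cutoff loop q-value cutoff (0.05).
#' @param loop_range loop distance range in bp (50 kb - 10 Mb).
#' @param tad_window TopDom-style diamond half-width in bins (5).
#' @param tad_p_cutoff TAD boundary p cutoff (0.05).
#' @param tad_tol_bp TAD boundary matching tolerance (80 kb).
#' @param tad_min_overlap reciprocal TAD overlap fraction (0.8).
#' @param top_n_peaks peak cap for TAD-state enrichment (30000).
#' @param top_n_enhancer,top_n_ctcf element ranking caps (25000 / 50000).
#' @param expressed_threshold mean log2(RPKM+1) cutoff (1.5).
#' @param fc_cutoff,alpha differential-expression thresholds (2, 0.05).
#' @param n_shuffles shuffle/random-set count for empirical nulls (100).
#' @param random_tad_size random-TAD size range (280-440 kb).
#' @param ice_max_iter,ice_tol,low_coverage_filter ICE settings.
#' @return list of class \code{pipeline_params}.
#' @export
pipeline_params <- function(fine_resolution = 1e4, coarse_resolution = 4e4,
                            q_cutoff = 0.05, loop_range = c(5e4, 1e7),
                            tad_window = 5, tad_p_cutoff = 0.05,
                            tad_tol_bp = 8e4, tad_min_overlap = 0.8,
                            top_n_peaks = 30000, top_n_enhancer = 25000,
                            top_n_ctcf = 50000, expressed_threshold = 1.5,
                            fc_cutoff = 2, alpha = 0.05, n_shuffles = 100,
                            random_tad_size = c(280000, 440000),
                            ice_max_iter = 200, ice_tol = 1e-4,
                            low_coverage_filter = 0.02) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Run the full comparative 3D-epigenome pipeline
#'
#' Takes a three-condition dataset (first condition = normal line), runs
#' ICE normalization at both resolutions, TAD calling and cross-line
#' classification, TAD state annotation and state-change detection, loop
#' calling and anchor annotation, specificity classification of
#' enhancer-promoter loops, differential loop and expression tests, and the
#' empirical nulls; writes every tabular output plus a run manifest to
#' \code{outdir} and returns all results. Deterministic under \code{seed}.
#'
#' @param dataset a \code{hic_dataset} from \code{\link{simulate_dataset}}
#'   (or an equivalent list built from files read with the genome-io
#'   readers).
#' @param outdir output directory.
#' @param params a \code{\link{pipeline_params}}.
#' @param seed root seed for the empirical nulls.
#' @return invisibly, a list with every intermediate and final result.
#' @export
run_pipeline <- function(dataset, outdir, params = pipeline_params(), seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  conds <- dataset$config$conditions
  stopifnot(length(conds) == 3L)
  normal <- conds[1]
  genes <- dataset$genes
  res <- list(params = params, seed = seed, conditions = conds)

  # --- normalization (per condition, both resolutions) ---
  fac <- params$coarse_resolution / params$fine_resolution
  norm10 <- list(); norm40 <- list(); decays <- list()
  for (cond in conds) {
    raw <- dataset$matrices[[cond]]
    ice10 <- ice_normalize(raw, max_iter = params$ice_max_iter,
                           tol = params$ice_tol,
                           low_coverage_filter = params$low_coverage_filter)
    ice40 <- ice_normalize(coarsen(raw, fac), max_iter = params$ice_max_iter,
                           tol = params$ice_tol,
                           low_coverage_filter = params$low_coverage_filter)
    norm10[[cond]] <- ice10$matrix
    norm40[[cond]] <- ice40$matrix
    decays[[cond]] <- estimate_decay(ice10$matrix, range = params$loop_range)
  }
  res$norm10 <- norm10; res$norm40 <- norm40; res$decays <- decays

  # --- TAD calling and classification ---
  tads <- lapply(conds, function(cond)
    call_tads(norm40[[cond]], window = params$tad_window,
              p_cutoff = params$tad_p_cutoff))
  names(tads) <- conds
  res$tads <- tads
  classification <- match_tads(tads, tol_bp = params$tad_tol_bp,
                               min_overlap = params$tad_min_overlap)
  res$classification <- classification
  res$size_tests <- tryCatch(compare_tad_sizes(classification),
                             error = function(e) NULL)
  res$split_tads <- detect_split_tads(tads[[normal]], tads[[conds[2]]],
                                      min_overlap = params$tad_min_overlap,
                                      genes = genes)

  # --- TAD states and changes ---
  marks <- c("H3K36me3", "H3K27me3", "H3K9me3")
  states <- lapply(conds, function(cond) {
    ann <- dataset$annotations[[cond]]
    classify_tad_states(tads[[cond]], ann$peaks[marks], ann$tracks[marks],
                        top_n = params$top_n_peaks)
  })
  names(states) <- conds
  res$states <- states
  res$gene_density <- lapply(conds, function(cond) {
    cls <- gene_density_class(tads[[cond]], genes)
    data.frame(tads[[cond]][, c("chrom", "start", "end")],
               n_genes = attr(cls, "n_genes"), class = cls)
  })
  names(res$gene_density) <- conds

  # state changes on common TADs (annotate the SAME normal-line intervals in
  # both conditions)
  chains <- classification$chains
  common <- chains[chains$class == "common", , drop = FALSE]
  if (nrow(common) > 0L) {
    common_tads <- tads[[normal]][common$normal_idx, , drop = FALSE]
    ann_n <- classify_tad_states(common_tads,
                                 dataset$annotations[[normal]]$peaks[marks],
                                 dataset$annotations[[normal]]$tracks[marks],
                                 top_n = params$top_n_peaks)
    ann_c <- classify_tad_states(common_tads,
                                 dataset$annotations[[conds[2]]]$peaks[marks],
                                 dataset$annotations[[conds[2]]]$tracks[marks],
                                 top_n = params$top_n_peaks)
    res$state_changes <- detect_state_changes(ann_n, ann_c, genes = genes)
  }

  # random-TAD empirical null for H3K36me3-enriched TADs (normal line)
  chrom_sizes <- dataset$config$chrom_sizes
  enrich_count <- function(tset) {
    ann <- dataset$annotations[[normal]]
    st <- suppressWarnings(
      classify_tad_states(tset, ann$peaks[marks], ann$tracks[marks],
                          top_n = params$top_n_peaks))
    sum(st$H3K36me3_enriched)
  }
  observed_enr <- sum(states[[normal]]$H3K36me3_enriched)
  res$random_tad_null <- random_tad_null(
    chrom_sizes, n_tads = nrow(tads[[normal]]), enrich_count = enrich_count,
    observed = observed_enr, n_sets = params$n_shuffles,
    size_range = params$random_tad_size, seed = substream_seed(seed, "tadnull"))

  # --- expression and regulatory element sets ---
  expr_cols <- lapply(conds, function(cond)
    paste0(cond, "_rep", seq_len(dataset$config$n_replicates)))
  names(expr_cols) <- conds
  rpkm_by_cond <- lapply(expr_cols, function(cc) as.matrix(genes[, cc]))
  expressed <- lapply(rpkm_by_cond, call_expressed,
                      threshold = params$expressed_threshold)
  res$expressed <- expressed
  reg_sets <- lapply(conds, function(cond) {
    ann <- dataset$annotations[[cond]]
    build_regulatory_sets(genes, expressed[[cond]], ann$peaks$H3K27ac,
                          ann$ctcf, top_n_enhancer = params$top_n_enhancer,
                          top_n_ctcf = params$top_n_ctcf)
  })
  names(reg_sets) <- conds
  res$reg_sets <- reg_sets

  # --- loops ---
  loops <- lapply(conds, function(cond) {
    lp <- call_significant_loops(norm10[[cond]], decays[[cond]],
                                 q_cutoff = params$q_cutoff,
                                 range = params$loop_range)
    annotate_anchors(lp, reg_sets[[cond]])
  })
  names(loops) <- conds
  res$loops <- loops
  res$top20 <- lapply(loops, top_categories, n = 20)
  res$fates <- lapply(conds, function(cond)
    loop_fate_fractions(reg_sets[[cond]], loops[[cond]]))
  names(res$fates) <- conds
  res$shuffle_null <- shuffle_anchor_null(
    loops[[normal]], reg_sets[[normal]],
    chrom = names(chrom_sizes)[1], chrom_length = chrom_sizes[[1]],
    n = params$n_shuffles, anchor_size = params$fine_resolution,
    seed = substream_seed(seed, "anchornull"))

  # --- E-P loop specificity and differential tests ---
  ep <- classify_ep_loops(loops)
  res$ep_loops <- ep
  if (nrow(ep) > 0L) {
    raws <- lapply(conds, function(cond) dataset$matrices[[cond]])
    names(raws) <- conds
    totals <- vapply(raws, in_range_total, numeric(1), range = params$loop_range)
    kraw <- vapply(conds, function(cond) {
      lp <- data.frame(chrom = ep$chrom, bin1 = NA_integer_, bin2 = NA_integer_)
      lp$bin1 <- ep$start1 %/% params$fine_resolution + 1L
      lp$bin2 <- ep$start2 %/% params$fine_resolution + 1L
      loop_raw_counts(lp, raws[[cond]])
    }, numeric(nrow(ep)))
    if (is.null(dim(kraw))) kraw <- matrix(kraw, nrow = nrow(ep))
    colnames(kraw) <- conds
    d1 <- differential_loop_test(kraw[, conds[2]], totals[conds[2]],
                                 kraw[, normal], totals[normal])
    d2 <- differential_loop_test(kraw[, conds[3]], totals[conds[3]],
                                 kraw[, normal], totals[normal])
    res$differential_loops <- data.frame(
      key = ep$key, specificity = ep$specificity,
      or_cancer1 = d1$odds_ratio, adj_p_cancer1 = d1$adj_p,
      or_cancer2 = d2$odds_ratio, adj_p_cancer2 = d2$adj_p,
      significant = d1$adj_p < params$alpha & d2$adj_p < params$alpha &
        ((d1$odds_ratio > 1) == (d2$odds_ratio > 1)))
  }

  # TF-bound looped enhancers (cancer-specific loops, first cancer line)
  cs_keys <- ep$key[ep$specificity == "cancer_specific"]
  lp_c1 <- loops[[conds[2]]]
  res$tf_bound <- tf_bound_looped_enhancers(
    lp_c1[loop_keys(lp_c1) %in% cs_keys, , drop = FALSE],
    reg_sets[[conds[2]]], dataset$annotations[[conds[2]]]$tf_peaks,
    genes = genes, ndrs = dataset$annotations[[conds[2]]]$ndrs)

  # --- expression consequences ---
  de <- differential_expression(rpkm_by_cond[[conds[2]]],
                                rpkm_by_cond[[normal]],
                                fc_cutoff = params$fc_cutoff,
                                alpha = params$alpha)
  de <- cbind(gene_id = genes$gene_id, de)
  res$de <- de
  fold_changes <- stats::setNames(de$log2fc, de$gene_id)
  ep_promoter_genes <- function(spec) {
    keys <- ep$key[ep$specificity == spec]
    sub <- ep[ep$key %in% keys, , drop = FALSE]
    if (nrow(sub) == 0L) return(character(0))
    anchors <- rbind(
      data.frame(chrom = sub$chrom, start = sub$start1, end = sub$end1),
      data.frame(chrom = sub$chrom, start = sub$start2, end = sub$end2))
    prom <- gene_promoters(genes)
    hit <- overlap_pairs(anchors, prom)
    unique(prom$name[hit$subject])
  }
  sets <- list(common = ep_promoter_genes("common"),
               normal_specific = ep_promoter_genes("normal_specific"),
               cancer_specific = ep_promoter_genes("cancer_specific"))
  sets$background <- setdiff(genes$gene_id, unlist(sets))
  sets <- sets[lengths(sets) >= 2L]
  res$geneset_tests <- tryCatch(compare_gene_sets(fold_changes, sets),
                                error = function(e) NULL)

  # --- ground-truth comparison when available ---
  if (!is.null(dataset$truth)) res$recovery <- recovery_summary(res, dataset)

  .write_pipeline_outputs(res, dataset, outdir)
  invisible(res)
}

# Recovery metrics against the planted ground truth.
recovery_summary <- function(res, dataset) {
  truth <- dataset$truth
  cfg <- dataset$config
  normal <- cfg$conditions[1]
  out <- list()
  # TAD boundary recovery (normal line, +/- 1 coarse bin)
  called <- res$tads[[normal]]
  cres <- attr(called, "resolution")
  planted <- truth$tads_normal
  planted_bounds <- unique(paste0(planted$chrom, ":",
                                  c(planted$start, planted$end)))
  pb <- do.call(rbind, strsplit(planted_bounds, ":"))
  pb <- data.frame(chrom = pb[, 1], pos = as.numeric(pb[, 2]))
  called_bounds <- unique(rbind(data.frame(chrom = called$chrom, pos = called$start),
                                data.frame(chrom = called$chrom, pos = called$end)))
  near <- function(q, ref) vapply(seq_len(nrow(q)), function(r) {
    any(ref$chrom == q$chrom[r] & abs(ref$pos - q$pos[r]) <= cres)
  }, logical(1))
  interior <- pb$pos > 0 & pb$pos < cfg$chrom_length
  out$tad_boundary_recovery <- mean(near(pb[interior, ], called_bounds))
  interior_called <- called_bounds$pos > 0 & called_bounds$pos < cfg$chrom_length
  out$tad_spurious_rate <- mean(!near(called_bounds[interior_called, ], pb))
  # planted-loop recovery per condition + empirical FDR vs planted pairs
  for (cond in cfg$conditions) {
    keep <- if (cond == normal) c("common", "normal_specific") else
      c("common", "cancer_specific")
    pl <- truth$loops[truth$loops$class %in% keep, ]
    pkeys <- sprintf("%s:%d-%d", pl$chrom, as.integer(pl$start1),
                     as.integer(pl$start2))
    ckeys <- loop_keys(res$loops[[cond]])
    out[[paste0("loop_sensitivity_", cond)]] <- mean(pkeys %in% ckeys)
    # on full-structure matrices most non-planted calls are genuine within-TAD
    # enrichments, so this is a call-composition figure, not an error rate
    out[[paste0("loop_nonplanted_call_fraction_", cond)]] <-
      if (length(ckeys) > 0) mean(!(ckeys %in% pkeys)) else 0
  }
  # E-P specificity recovery
  ep <- res$ep_loops
  cs <- truth$loops[truth$loops$class == "cancer_specific", ]
  cs_keys <- sprintf("%s:%d-%d", cs$chrom, as.integer(cs$start1),
                     as.integer(cs$start2))
  out$ep_cancer_specific_sensitivity <-
    mean(cs_keys %in% ep$key[ep$specificity == "cancer_specific"])
  out$ep_normal_mislabels <-
    sum(cs_keys %in% ep$key[ep$specificity == "normal_specific"])
  as.data.frame(out)
}

.write_pipeline_outputs <- function(res, dataset, outdir) {
  conds <- res$conditions
  for (cond in conds) {
    td <- res$tads[[cond]]
    td$name <- cond
    write_bed(td[, c("chrom", "start", "end", "name")],
              file.path(outdir, paste0("tads_", cond, ".bed")))
    write_loops_bedpe(res$loops[[cond]],
                      file.path(outdir, paste0("loops_", cond, ".bedpe")))
    write_tsv(res$top20[[cond]], file.path(outdir, paste0("top20_", cond, ".tsv")))
    write_tsv(res$fates[[cond]], file.path(outdir, paste0("fates_", cond, ".tsv")))
    write_tsv(res$states[[cond]], file.path(outdir, paste0("states_", cond, ".tsv")))
    write_tsv(res$gene_density[[cond]],
              file.path(outdir, paste0("gene_density_", cond, ".tsv")))
  }
  write_tsv(res$classification$chains, file.path(outdir, "tad_classification.tsv"))
  if (!is.null(res$size_tests)) {
    write_tsv(res$size_tests, file.path(outdir, "tad_size_tests.tsv"))
  }
  write_tsv(res$split_tads, file.path(outdir, "split_tads.tsv"))
  if (!is.null(res$state_changes)) {
    write_tsv(res$state_changes$tads, file.path(outdir, "state_changes.tsv"))
    write_tsv(res$state_changes$fractions,
              file.path(outdir, "state_change_fractions.tsv"))
    if (!is.null(res$state_changes$tests)) {
      write_tsv(res$state_changes$tests,
                file.path(outdir, "state_change_tests.tsv"))
    }
  }
  if (!is.null(res$ep_loops) && nrow(res$ep_loops) > 0L) {
    write_tsv(res$ep_loops, file.path(outdir, "ep_loops.tsv"))
  }
  if (!is.null(res$differential_loops)) {
    write_tsv(res$differential_loops, file.path(outdir, "differential_loops.tsv"))
  }
  write_tsv(res$de, file.path(outdir, "differential_expression.tsv"))
  if (!is.null(res$geneset_tests)) {
    write_tsv(res$geneset_tests, file.path(outdir, "geneset_tests.tsv"))
  }
  write_tsv(res$shuffle_null, file.path(outdir, "shuffle_anchor_null.tsv"))
  if (!is.null(res$recovery)) {
    write_tsv(res$recovery, file.path(outdir, "recovery_summary.tsv"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("hicstates")),
    seed = res$seed,
    conditions = conds,
    params = res$params[setdiff(names(res$params), "class")],
    counts = list(
      tads = lapply(res$tads, nrow),
      loops = lapply(res$loops, nrow),
      ep_loops = if (!is.null(res$ep_loops)) nrow(res$ep_loops) else 0L,
      tad_classes = as.list(res$classification$counts),
      random_tad_null_p = res$random_tad_null$p),
    outputs = list.files(outdir))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
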