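# Readers/writers for the external formats the pipeline touches (BED, BEDPE,
# HiC-Pro-style triplet matrices with a companion bin BED, gene tables) and
# the shared binned contact-matrix container.
#
# Coordinate convention: 0-based half-open everywhere, i.e. the native BED
# convention. Any 1-based format would be converted at the boundary.

#' Read a BED file of genomic intervals
#'
#' Parses a 3-6 column tab-separated BED file into a data.frame of 0-based
#' half-open intervals. Input order is preserved; optional name/score/strand
#' columns are kept when present.
#'
#' @param path path to a BED file.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end} and,
#'   when present, \code{name}, \code{score}, \code{strand}.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  bad <- which(ncol < 3L)
  if (length(bad) > 0L) stop("malformed BED line ", bad[1], ": fewer than 3 columns")
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(end <= start | start < 0)
  if (length(bad) > 0L) {
    stop("invalid interval at BED line ", bad[1], ": requires 0 <= start < end")
  }
  out <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = start, end = end, stringsAsFactors = FALSE
  )
  if (all(ncol >= 4L)) out$name <- vapply(fields, `[[`, "", 4L)
  if (all(ncol >= 5L)) out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (all(ncol >= 6L)) out$strand <- vapply(fields, `[[`, "", 6L)
  out
}

#' Write intervals as BED
#'
#' @param df data.frame with \code{chrom}, \code{start}, \code{end} and
#'   optional \code{name}, \code{score}, \code{strand} columns.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end")
  for (opt in c("name", "score", "strand")) {
    if (opt %in% names(df)) cols <- c(cols, opt) else break
  }
  out <- df[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a binned Hi-C contact matrix
#'
#' The canonical container for binned intra-chromosomal contact counts.
#' Entries are stored as an upper-triangle triplet list (\code{i <= j}, indices
#' into the bin table); duplicate entries are summed, non-positive counts are
#' dropped, and lower-triangle entries are mirrored during canonicalization.
#'
#' @param bins data.frame with \code{chrom}, \code{start}, \code{end} and
#'   \code{bin_id} (the external id used in triplet files); bins must tile
#'   each chromosome contiguously (the last bin may be short).
#' @param i,j integer vectors of bin-table row indices.
#' @param x numeric vector of non-negative counts.
#' @param resolution bin width in bp.
#' @param bias optional per-bin positive bias vector (NA for masked bins).
#' @param mask optional logical vector of masked (excluded) bins.
#' @param normalized logical; TRUE after ICE balancing.
#' @return object of class \code{hic_matrix}.
#' @export
hic_matrix <- function(bins, i, j, x, resolution, bias = NULL, mask = NULL,
                       normalized = FALSE) {
  stopifnot(all(c("chrom", "start", "end", "bin_id") %in% names(bins)))
  n <- nrow(bins)
  i <- as.integer(i); j <- as.integer(j); x <- as.numeric(x)
  stopifnot(length(i) == length(j), length(j) == length(x))
  if (length(i) > 0L) {
    if (any(i < 1L | i > n | j < 1L | j > n)) stop("bin index out of range")
    if (any(x < 0)) stop("negative contact count")
    if (any(bins$chrom[i] != bins$chrom[j])) {
      stop("inter-chromosomal entries are not supported")
    }
    sw <- i > j
    tmp <- i[sw]; i[sw] <- j[sw]; j[sw] <- tmp
    keep <- x > 0
    i <- i[keep]; j <- j[keep]; x <- x[keep]
    if (length(i) > 0L) {
      key <- (as.numeric(i) - 1) * n + as.numeric(j)
      if (anyDuplicated(key)) {
        agg <- rowsum(x, group = key)
        key_u <- as.numeric(rownames(agg))
        x <- as.numeric(agg[, 1])
        i <- as.integer((key_u - 1) %/% n + 1)
        j <- as.integer((key_u - 1) %% n + 1)
      }
      o <- order(i, j)
      i <- i[o]; j <- j[o]; x <- x[o]
    }
  }
  structure(list(bins = bins, i = i, j = j, x = x, resolution = resolution,
                 bias = bias, mask = mask, normalized = normalized),
            class = "hic_matrix")
}

#' @export
print.hic_matrix <- function(x, ...) {
  cat(sprintf("hic_matrix: %d bins (%s), resolution %d bp, %d entries, mass %.4g%s\n",
              nrow(x$bins), paste(unique(x$bins$chrom), collapse = ","),
              as.integer(x$resolution), length(x$x), sum(x$x),
              if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' Build a bin table tiling chromosomes at a fixed resolution
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param resolution bin width in bp; the last bin of a chromosome may be short.
#' @return bin table data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{bin_id}); ids are dense and 1-based in chromosome order.
#' @export
make_bin_table <- function(chrom_sizes, resolution) {
  stopifnot(length(names(chrom_sizes)) == length(chrom_sizes), resolution > 0)
  pieces <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = resolution)
    data.frame(chrom = ch, start = starts, end = pmin(starts + resolution, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$bin_id <- seq_len(nrow(bins))
  bins
}

#' Read a HiC-Pro style triplet contact matrix
#'
#' The matrix file holds whitespace-separated triplets \code{bin_i bin_j count};
#' the companion bin BED maps ids to coordinates (4th column = bin id). Lower
#' triangle entries are mirrored into canonical upper-triangle storage and
#' duplicate pairs are summed.
#'
#' @param matrix_path triplet file.
#' @param bins_path companion bin BED.
#' @return a \code{\link{hic_matrix}}.
#' @export
read_contact_matrix <- function(matrix_path, bins_path) {
  bed <- read_bed(bins_path)
  if (!"name" %in% names(bed)) stop("bin BED requires a 4th column with bin ids")
  bins <- data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
                     bin_id = as.integer(bed$name), stringsAsFactors = FALSE)
  resolution <- max(bins$end - bins$start)
  trip <- tryCatch(
    utils::read.table(matrix_path, header = FALSE,
                      colClasses = c("integer", "integer", "numeric")),
    error = function(e) data.frame(V1 = integer(0), V2 = integer(0), V3 = numeric(0)))
  if (nrow(trip) > 0L && any(trip$V3 < 0)) stop("negative contact count in matrix file")
  idx <- match(trip$V1, bins$bin_id)
  jdx <- match(trip$V2, bins$bin_id)
  if (anyNA(idx) || anyNA(jdx)) stop("triplet references a bin id absent from the bin table")
  hic_matrix(bins, idx, jdx, trip$V3, resolution)
}

#' Write a contact matrix as HiC-Pro style triplets plus a bin BED
#'
#' @param mat a \code{hic_matrix}.
#' @param matrix_path,bins_path output paths.
#' @export
write_contact_matrix <- function(mat, matrix_path, bins_path) {
  b <- mat$bins
  write_bed(data.frame(chrom = b$chrom, start = b$start, end = b$end,
                       name = b$bin_id), bins_path)
  trip <- data.frame(i = b$bin_id[mat$i], j = b$bin_id[mat$j],
                     x = format(mat$x, scientific = FALSE, trim = TRUE, digits = 10))
  utils::write.table(trip, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(matrix_path)
}

# --- contact-matrix accessors -------------------------------------------------

# Row indices of a chromosome's bins.
cm_chrom_rows <- function(mat, chrom) which(mat$bins$chrom == chrom)

cm_chroms <- function(mat) unique(mat$bins$chrom)

# Total mass: each stored (upper-triangle) entry counted once.
cm_total <- function(mat) sum(mat$x)

# Dense symmetric matrix for one chromosome; masked bins set to NA.
cm_dense <- function(mat, chrom) {
  rows <- cm_chrom_rows(mat, chrom)
  n <- length(rows)
  off <- rows[1] - 1L
  D <- matrix(0, n, n)
  sel <- mat$i >= rows[1] & mat$i <= rows[n]
  ii <- mat$i[sel] - off; jj <- mat$j[sel] - off; xx <- mat$x[sel]
  D[cbind(ii, jj)] <- xx
  D[cbind(jj, ii)] <- xx
  if (!is.null(mat$mask)) {
    mk <- which(mat$mask[rows])
    if (length(mk) > 0L) { D[mk, ] <- NA_real_; D[, mk] <- NA_real_ }
  }
  D
}

# Marginal (row sum over the full symmetric matrix, diagonal once) per bin.
cm_marginals <- function(mat) {
  n <- nrow(mat$bins)
  m <- numeric(n)
  if (length(mat$x) > 0L) {
    agg <- rowsum(mat$x, mat$i)
    m[as.integer(rownames(agg))] <- agg[, 1]
    off <- mat$i != mat$j
    if (any(off)) {
      agg <- rowsum(mat$x[off], mat$j[off])
      idx <- as.integer(rownames(agg))
      m[idx] <- m[idx] + agg[, 1]
    }
  }
  m
}

# --- gene tables --------------------------------------------------------------

#' Read a gene table with expression columns
#'
#' Tab-separated with header: \code{gene_id}, \code{chrom}, \code{strand},
#' \code{tss} (0-based bp), \code{length} (bp, for RPKM), followed by one
#' numeric expression column per condition/replicate (e.g.
#' \code{normal_rep1}). Expression values are RPKM.
#'
#' @param path input TSV.
#' @return data.frame; expression column names are stored in the
#'   \code{"expr_cols"} attribute.
#' @export
read_gene_table <- function(path) {
  g <- read_tsv(path)
  need <- c("gene_id", "chrom", "strand", "tss", "length")
  if (!all(need %in% names(g))) {
    stop("gene table requires columns: ", paste(need, collapse = ", "))
  }
  if (any(g$length <= 0)) stop("gene_length must be positive")
  attr(g, "expr_cols") <- setdiff(names(g), need)
  g
}

#' Write a gene table
#' @param genes data.frame as returned by \code{\link{read_gene_table}}.
#' @param path output TSV.
#' @export
write_gene_table <- function(genes, path) write_tsv(genes, path)

# Promoter windows (TSS +/- halfwidth, clipped at 0) for a gene table.
gene_promoters <- function(genes, halfwidth = 2000) {
  data.frame(chrom = genes$chrom,
             start = pmax(0, genes$tss - halfwidth),
             end = genes$tss + halfwidth,
             name = genes$gene_id, stringsAsFactors = FALSE)
}

# --- loops (BEDPE) ------------------------------------------------------------

#' Write loops as 10+ column BEDPE
#'
#' Standard BEDPE columns (both anchors 0-based half-open) followed by the
#' normalized count, p-value, q-value and anchor category.
#'
#' @param loops annotated loop data.frame (see \code{\link{call_significant_loops}}).
#' @param path output path.
#' @export
write_loops_bedpe <- function(loops, path) {
  need <- c("chrom", "start1", "end1", "start2", "end2")
  if (!all(need %in% names(loops))) stop("loops lack resolved anchor coordinates")
  if (nrow(loops) > 0L && anyNA(loops[, need])) stop("unresolvable loop anchor")
  if ("chrom2" %in% names(loops) && any(loops$chrom2 != loops$chrom)) {
    stop("inter-chromosomal loops are not supported (intra-chromosomal only)")
  }
  n <- nrow(loops)
  out <- data.frame(
    chrom1 = loops$chrom, start1 = loops$start1, end1 = loops$end1,
    chrom2 = loops$chrom, start2 = loops$start2, end2 = loops$end2,
    name = if ("name" %in% names(loops)) loops$name else sprintf("loop_%d", seq_len(n)),
    score = if ("count" %in% names(loops)) signif(loops$count, 8) else rep(0, n),
    strand1 = rep(".", n), strand2 = rep(".", n),
    count = if ("count" %in% names(loops)) signif(loops$count, 8) else rep(NA_real_, n),
    p = if ("p" %in% names(loops)) signif(loops$p, 8) else rep(NA_real_, n),
    q = if ("q" %in% names(loops)) signif(loops$q, 8) else rep(NA_real_, n),
    category = if ("category" %in% names(loops)) loops$category else rep(".", n))
  for (cc in c("start1", "end1", "start2", "end2")) {
    out[[cc]] <- format(out[[cc]], scientific = FALSE, trim = TRUE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read loops from BEDPE written by \code{\link{write_loops_bedpe}}
#' @param path BEDPE path.
#' @return loop data.frame.
#' @export
read_loops_bedpe <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 10L) stop("BEDPE requires at least 10 columns")
  out <- data.frame(
    chrom = raw$V1, start1 = raw$V2, end1 = raw$V3,
    start2 = raw$V5, end2 = raw$V6, name = raw$V7, stringsAsFactors = FALSE)
  if (any(raw$V4 != raw$V1)) stop("inter-chromosomal loops are not supported")
  if (ncol(raw) >= 14L) {
    out$count <- as.numeric(raw$V11); out$p <- as.numeric(raw$V12)
    out$q <- as.numeric(raw$V13); out$category <- raw$V14
  }
  out$distance <- out$start2 - out$start1
  out
}
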