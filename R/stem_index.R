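#' Quality-control filter for a gene-count matrix
#'
#' Removes low-quality cells using the printed exclusion bounds, all
#' strict: more than 32,500 or fewer than 1,000 UMIs; more than 7,000 or
#' fewer than 300 detected genes; more than 20% mitochondrial
#' transcripts; UMI/read ratio above 0.4. Cells exactly at a bound are
#' kept. Genes detected in fewer than 25 cells are then removed
#' (gene filter after cell filters). The per-rule report attributes each
#' removed cell to the first failing rule in the order
#' UMI -> genes -> mito -> ratio; the kept set itself is
#' order-independent.
#'
#' UMI totals, detected-gene counts and mitochondrial fractions are
#' recomputed from the matrix (mitochondrial genes carry an `MT-` name
#' prefix); the UMI/read ratio must come from `metadata`.
#'
#' @param counts cells x genes non-negative integer matrix (dense or
#'   [Matrix::Matrix]) with gene names as column names.
#' @param metadata optional data.frame aligned with rows, with column
#'   `umi_read_ratio` (cells lacking it skip the ratio rule).
#' @param max_umis,min_umis,max_genes,min_genes,max_mito_fraction,max_umi_read_ratio
#'   exclusion bounds (strict inequalities).
#' @param min_cells_per_gene genes detected in fewer than this many kept
#'   cells are dropped.
#' @return list with `counts` (filtered matrix), `metadata` (filtered,
#'   if given) and `report` (named counts: kept, removed_umi,
#'   removed_genes, removed_mito, removed_ratio, genes_removed;
#'   kept + removed_* = input cells).
#' @export
qc_filter <- function(counts, metadata = NULL,
                      max_umis = 32500, min_umis = 1000,
                      max_genes = 7000, min_genes = 300,
                      max_mito_fraction = 0.20,
                      max_umi_read_ratio = 0.4,
                      min_cells_per_gene = 25) {
  n <- nrow(counts)
  total <- as.numeric(Matrix::rowSums(counts))
  ngene <- as.numeric(Matrix::rowSums(counts > 0))
  mito_cols <- grepl("^MT-", colnames(counts))
  mito <- if (any(mito_cols)) {
    as.numeric(Matrix::rowSums(counts[, mito_cols, drop = FALSE])) /
      pmax(total, 1)
  } else rep(0, n)
  ratio <- if (!is.null(metadata) && "umi_read_ratio" %in% names(metadata)) {
    metadata$umi_read_ratio
  } else rep(0, n)

  fail_umi <- total > max_umis | total < min_umis
  fail_genes <- ngene > max_genes | ngene < min_genes
  fail_mito <- mito > max_mito_fraction
  fail_ratio <- ratio > max_umi_read_ratio
  keep <- !(fail_umi | fail_genes | fail_mito | fail_ratio)
  # attribution with fixed precedence, for the report only
  first <- rep(NA_character_, n)
  first[fail_ratio] <- "ratio"
  first[fail_mito] <- "mito"
  first[fail_genes] <- "genes"
  first[fail_umi] <- "umi"
  report <- c(
    kept = sum(keep),
    removed_umi = sum(first == "umi", na.rm = TRUE),
    removed_genes = sum(first == "genes", na.rm = TRUE),
    removed_mito = sum(first == "mito", na.rm = TRUE),
    removed_ratio = sum(first == "ratio", na.rm = TRUE)
  )
  counts <- counts[keep, , drop = FALSE]
  if (!is.null(metadata)) metadata <- metadata[keep, , drop = FALSE]
  gene_keep <- if (nrow(counts)) {
    as.numeric(Matrix::colSums(counts > 0)) >= min_cells_per_gene
  } else rep(TRUE, ncol(counts))
  report <- c(report, genes_removed = sum(!gene_keep))
  counts <- counts[, gene_keep, drop = FALSE]
  list(counts = counts, metadata = metadata, report = report)
}

#' Count-based normalisation excluding highly expressed genes
#'
#' Per cell, genes individually exceeding `highly_expressed_cutoff` of
#' that cell's total are excluded from the size-factor sum: the size
#' factor is (total excluding those genes) / `scale_factor`, and every
#' gene's count — including excluded ones — is divided by it. Cells in
#' which no counted gene remains are dropped with a warning. The
#' natural-log transform is a separate step, see [log_transform()].
#'
#' @param counts cells x genes non-negative matrix.
#' @param scale_factor target size (default 10,000).
#' @param highly_expressed_cutoff per-cell fraction above which a gene is
#'   excluded from the size factor (default 0.05).
#' @return normalised real matrix with attribute `steps = "normalized"`.
#' @export
normalize_counts <- function(counts, scale_factor = 10000,
                             highly_expressed_cutoff = 0.05) {
  total <- as.numeric(Matrix::rowSums(counts))
  # per-cell excluded mass: sum of entries exceeding cutoff * cell total
  dense <- as.matrix(counts)
  he <- dense > highly_expressed_cutoff * total
  excl <- rowSums(dense * he)
  base <- total - excl
  drop <- base <= 0 & total > 0
  if (any(drop)) {
    warning(sum(drop), " cell(s) with no countable genes dropped")
  }
  keep <- !drop
  dense <- dense[keep, , drop = FALSE]
  sf <- base[keep] / scale_factor
  sf[sf == 0] <- 1  # all-zero cells pass through unchanged
  out <- dense / sf
  attr(out, "steps") <- "normalized"
  out
}

#' Natural-log transform, ln(1 + x)
#'
#' Recorded as its own processing step after [normalize_counts()].
#' @param normalized matrix from [normalize_counts()].
#' @return log-transformed matrix with `steps` extended by `"log1p"`.
#' @export
log_transform <- function(normalized) {
  steps <- attr(normalized, "steps")
  if ("log1p" %in% steps) stop("state error: already log-transformed")
  out <- log1p(normalized)
  attr(out, "steps") <- c(steps, "log1p")
  out
}

#' Score a gene program against bin-matched control genes
#'
#' Genes are ranked by mean expression across cells and split into
#' `n_bins` equal-size bins; for each program gene,
#' `n_control_per_gene` control genes are sampled (seeded, without
#' replacement) from its bin, excluding all program genes. The per-cell
#' score is the mean expression of the program genes minus the mean
#' expression of the pooled control genes — positive when the program is
#' elevated relative to expression-matched background.
#'
#' @param lognorm cells x genes log-normalised matrix.
#' @param program_genes character vector; genes absent from the matrix
#'   are dropped with a warning (an empty program is an error).
#' @param n_control_per_gene controls sampled per program gene
#'   (default 50, truncated to bin occupancy).
#' @param n_bins expression bins (default 25).
#' @param seed seed for control sampling (default 0).
#' @return numeric per-cell score vector.
#' @export
score_gene_program <- function(lognorm, program_genes,
                               n_control_per_gene = 50, n_bins = 25,
                               seed = 0) {
  genes <- colnames(lognorm)
  missing <- setdiff(program_genes, genes)
  if (length(missing)) {
    warning(length(missing), " program gene(s) absent and dropped: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  program_genes <- intersect(program_genes, genes)
  if (!length(program_genes)) {
    stop("value error: program empty after dropping missing genes")
  }
  gene_means <- as.numeric(Matrix::colMeans(lognorm))
  bins <- ceiling(rank(gene_means, ties.method = "first") /
                    (length(gene_means) / n_bins))
  names(bins) <- genes
  old_seed <- .save_seed(); on.exit(.restore_seed(old_seed))
  set.seed(seed)
  control <- character(0)
  for (g in program_genes) {
    pool <- setdiff(genes[bins == bins[[g]]], program_genes)
    if (!length(pool)) next
    control <- c(control,
                 sample(pool, min(n_control_per_gene, length(pool))))
  }
  control <- unique(control)
  prog_mean <- as.numeric(Matrix::rowMeans(
    lognorm[, program_genes, drop = FALSE]))
  ctrl_mean <- if (length(control)) {
    as.numeric(Matrix::rowMeans(lognorm[, control, drop = FALSE]))
  } else rep(0, nrow(lognorm))
  prog_mean - ctrl_mean
}

#' Stem cell index: revCSC score minus proCSC score
#'
#' @param pro_scores,rev_scores per-cell program scores with matching
#'   cell names (or equal unnamed lengths).
#' @return per-cell index; positive values indicate revival-program
#'   dominance.
#' @export
stem_cell_index <- function(pro_scores, rev_scores) {
  if (length(pro_scores) != length(rev_scores)) {
    stop("value error: score vectors differ in length")
  }
  if (!is.null(names(pro_scores)) && !is.null(names(rev_scores)) &&
      !identical(names(pro_scores), names(rev_scores))) {
    stop("value error: cell id mismatch between score vectors")
  }
  rev_scores - pro_scores
}

#' Median and quartiles of a stem cell index, per sample
#' @param index per-cell index values.
#' @param sample per-cell sample labels (single sample if NULL).
#' @return data.frame with sample, q1, median, q3, n.
#' @export
stem_index_summary <- function(index, sample = NULL) {
  if (is.null(sample)) sample <- "all"
  sample <- rep_len(as.character(sample), length(index))
  out <- do.call(rbind, lapply(split(index, sample), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(q1 = q[1], median = q[2], q3 = q[3], n = length(v))
  }))
  out$sample <- rownames(out)
  rownames(out) <- NULL
  out[, c("sample", "q1", "median", "q3", "n")]
}
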