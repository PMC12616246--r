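#' Default proliferative (proCSC) and revival (revCSC) program gene sets
#'
#' Small literature-flavoured signatures for the synthetic gene universe:
#' the proliferative colorectal cancer stem-cell program is cell-cycle
#' driven, the revival program stress/fetal-like. Disjoint by
#' construction.
#' @return list with character vectors `proCSC` and `revCSC`.
#' @export
default_csc_programs <- function() {
  list(
    proCSC = c("MKI67", "CCNB1", "CCNA2", "CDK1", "TOP2A",
               "BIRC5", "PLK1", "AURKA", "MCM2", "PCNA"),
    revCSC = c("CLU", "ANXA1", "BASP1", "EMP1", "KRT17",
               "LAMC2", "TACSTD2", "F3", "IFITM3", "S100A4")
  )
}

#' Configuration for the synthetic scRNA-seq count generator
#'
#' @param n_cells number of cells (0 allowed: empty matrix with headers).
#' @param n_genes total genes in the universe, including the program
#'   genes and 13 mitochondrial (`MT-` prefixed) genes.
#' @param proCSC_genes,revCSC_genes disjoint program gene sets, both
#'   within the universe (defaults from [default_csc_programs()]).
#' @param program_mix per-cell weight in \[0,1\] toward the revCSC
#'   program; default `runif(n_cells)` drawn under the config seed.
#' @param program_amplitude fold-range of program modulation (mean
#'   program-gene expression scales with `1 + amplitude * weight`).
#' @param mean_umis_per_cell expected library size of an average cell.
#' @param mito_fraction_dist Beta parameters `c(shape1, shape2)` for the
#'   per-cell mitochondrial transcript fraction (default mean 5%).
#' @param umi_read_ratio_dist Beta parameters for the per-cell UMI/read
#'   ratio (default mean 0.3, below the 0.4 exclusion bound).
#' @param seed integer seed.
#' @return a `scrna_sim_config` list.
#' @export
scrna_sim_config <- function(n_cells, n_genes = 2000,
                             proCSC_genes = default_csc_programs()$proCSC,
                             revCSC_genes = default_csc_programs()$revCSC,
                             program_mix = NULL,
                             program_amplitude = 4,
                             mean_umis_per_cell = 5000,
                             mito_fraction_dist = c(2.5, 47.5),
                             umi_read_ratio_dist = c(6, 14),
                             seed = 1L) {
  if (length(intersect(proCSC_genes, revCSC_genes))) {
    stop("configuration error: proCSC and revCSC gene sets overlap")
  }
  mito_genes <- paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "ATP8",
                                "ATP6", "CO3", "ND3", "ND4L", "ND4",
                                "ND5", "ND6", "CYB"))
  named <- c(proCSC_genes, revCSC_genes, mito_genes)
  if (n_genes < length(named)) {
    stop("n_genes too small for the program and mitochondrial genes")
  }
  genes <- c(named, sprintf("GENE%04d", seq_len(n_genes - length(named))))
  if (!is.null(program_mix)) {
    if (length(program_mix) != n_cells ||
        any(program_mix < 0 | program_mix > 1)) {
      stop("program_mix must be n_cells values in [0, 1]")
    }
  }
  structure(list(
    n_cells = as.integer(n_cells), genes = genes,
    proCSC_genes = proCSC_genes, revCSC_genes = revCSC_genes,
    mito_genes = mito_genes, program_mix = program_mix,
    program_amplitude = program_amplitude,
    mean_umis_per_cell = mean_umis_per_cell,
    mito_fraction_dist = mito_fraction_dist,
    umi_read_ratio_dist = umi_read_ratio_dist,
    seed = as.integer(seed)
  ), class = "scrna_sim_config")
}

#' Generate a synthetic gene-count matrix with planted stem-cell programs
#'
#' Per-gene base means are Gamma-distributed; per-cell library sizes are
#' log-normal; counts are Poisson. Each cell's program weight `m` scales
#' revCSC-gene means by `1 + amplitude * m` and proCSC-gene means by
#' `1 + amplitude * (1 - m)`, so revCSC-dominated cells have elevated
#' revCSC and depressed proCSC counts. Mitochondrial (`MT-`) gene means
#' are set so each cell's expected mitochondrial fraction follows the
#' configured Beta distribution; the UMI/read ratio is drawn per cell.
#'
#' @param config a [scrna_sim_config()].
#' @return list with `counts` (cells x genes sparse integer
#'   [Matrix::Matrix], cell barcodes as row names), `metadata` (data.frame:
#'   barcode, total_umis, n_genes, mito_fraction, umi_read_ratio) and
#'   `truth` (per-cell `program_mix` and the planted gene sets).
#' @export
generate_scrna_counts <- function(config) {
  stopifnot(inherits(config, "scrna_sim_config"))
  old_seed <- .save_seed(); on.exit(.restore_seed(old_seed))
  set.seed(config$seed)
  genes <- config$genes
  n <- config$n_cells
  if (n == 0) {
    counts <- Matrix::Matrix(0, 0, length(genes), sparse = TRUE,
                             dimnames = list(character(0), genes))
    meta <- data.frame(barcode = character(0), total_umis = integer(0),
                       n_genes = integer(0), mito_fraction = numeric(0),
                       umi_read_ratio = numeric(0))
    return(list(counts = counts, metadata = meta,
                truth = list(program_mix = numeric(0),
                             proCSC_genes = config$proCSC_genes,
                             revCSC_genes = config$revCSC_genes)))
  }
  is_mito <- genes %in% config$mito_genes
  base <- stats::rgamma(length(genes), shape = 0.4, rate = 0.4)
  base[genes %in% c(config$proCSC_genes, config$revCSC_genes)] <-
    stats::rgamma(length(config$proCSC_genes) + length(config$revCSC_genes),
                  shape = 2, rate = 1) + 0.5
  base[is_mito] <- 0  # filled per cell from the target mito fraction
  m <- config$program_mix
  if (is.null(m)) m <- stats::runif(n)
  lib <- stats::rlnorm(n, 0, 0.3)
  amp <- config$program_amplitude
  mito_target <- stats::rbeta(n, config$mito_fraction_dist[1],
                              config$mito_fraction_dist[2])
  ratio <- stats::rbeta(n, config$umi_read_ratio_dist[1],
                        config$umi_read_ratio_dist[2])

  pro_idx <- match(config$proCSC_genes, genes)
  rev_idx <- match(config$revCSC_genes, genes)
  scale_per_cell <- config$mean_umis_per_cell / sum(base)
  counts <- matrix(0L, n, length(genes), dimnames = list(
    sprintf("CELL%05d", seq_len(n)), genes))
  for (i in seq_len(n)) {
    mu <- base
    mu[pro_idx] <- mu[pro_idx] * (1 + amp * (1 - m[i]))
    mu[rev_idx] <- mu[rev_idx] * (1 + amp * m[i])
    mu <- mu * scale_per_cell * lib[i]
    mu[is_mito] <- mito_target[i] / (1 - mito_target[i]) *
      sum(mu[!is_mito]) / sum(is_mito)
    counts[i, ] <- stats::rpois(length(genes), mu)
  }
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  meta <- data.frame(
    barcode = rownames(counts),
    total_umis = as.integer(Matrix::rowSums(counts)),
    n_genes = as.integer(Matrix::rowSums(counts > 0)),
    mito_fraction = as.numeric(
      Matrix::rowSums(counts[, is_mito, drop = FALSE]) /
        pmax(Matrix::rowSums(counts), 1)),
    umi_read_ratio = ratio,
    stringsAsFactors = FALSE
  )
  list(counts = counts, metadata = meta,
       truth = list(program_mix = m,
                    proCSC_genes = config$proCSC_genes,
                    revCSC_genes = config$revCSC_genes))
}

#' Write a gene-count matrix as MatrixMarket MTX with sidecar TSVs
#'
#' Writes `matrix.mtx` (genes x cells, the 10x/CellRanger orientation),
#' `genes.tsv`, `barcodes.tsv` and `metadata.tsv` into `dir`.
#'
#' @param sim output of [generate_scrna_counts()], or a list with
#'   `counts` and `metadata`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_gene_counts <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::t(sim$counts), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(sim$counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(sim$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a gene-count matrix written by [write_gene_counts()]
#' @param dir directory containing matrix.mtx, genes.tsv, barcodes.tsv
#'   and optionally metadata.tsv.
#' @return list with `counts` (cells x genes sparse matrix) and
#'   `metadata` (NULL if absent).
#' @export
read_gene_counts <- function(dir) {
  counts <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  counts <- methods::as(counts, "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "genes.tsv"))
  meta_path <- file.path(dir, "metadata.tsv")
  meta <- if (file.exists(meta_path)) {
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  } else NULL
  list(counts = counts, metadata = meta)
}
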