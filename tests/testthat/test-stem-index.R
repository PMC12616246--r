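test_that("QC exclusion bounds are strict and attributed in rule order", {
  genes <- c(paste0("G", 1:6), "MT-1")
  counts <- rbind(
    ok      = c(300, 300, 200, 100, 50, 30, 20),   # total 1000, mito 2%
    low_umi = c(100, 100, 100, 100, 50, 30, 19),   # total 499
    hi_mito = c(100, 100, 100, 100, 50, 30, 520),  # mito 52%
    hi_ratio = c(300, 300, 200, 100, 50, 30, 20))
  colnames(counts) <- genes
  md <- data.frame(umi_read_ratio = c(0.2, 0.2, 0.2, 0.9))
  out <- qc_filter(counts, md, min_genes = 2, min_cells_per_gene = 0)
  expect_identical(rownames(out$counts), "ok")
  expect_identical(unname(out$report[c("kept", "removed_umi",
                                       "removed_mito", "removed_ratio")]),
                   c(1L, 1L, 1L, 1L))
  expect_identical(sum(out$report[c("kept", "removed_umi", "removed_genes",
                                    "removed_mito", "removed_ratio")]),
                   4L)
  # boundary cells are kept: exactly 1000 UMIs, exactly 20% mito,
  # exactly 0.4 ratio
  b <- rbind(edge = c(500, 150, 100, 30, 10, 10, 200))
  colnames(b) <- genes
  outb <- qc_filter(b, data.frame(umi_read_ratio = 0.4),
                    min_genes = 2, min_cells_per_gene = 0)
  expect_identical(unname(outb$report[["kept"]]), 1L)
  # a cell failing both UMI and ratio is attributed to the UMI rule
  both <- rbind(bad = c(100, 100, 100, 100, 50, 30, 19))
  colnames(both) <- genes
  outc <- qc_filter(both, data.frame(umi_read_ratio = 0.9),
                    min_genes = 2, min_cells_per_gene = 0)
  expect_identical(unname(outc$report[["removed_umi"]]), 1L)
  expect_identical(unname(outc$report[["removed_ratio"]]), 0L)
})

test_that("genes in too few cells are dropped after cell filtering", {
  set.seed(91)
  counts <- matrix(rpois(50 * 10, 200), 50, 10,
                   dimnames = list(NULL, paste0("G", 1:10)))
  counts[, "G10"] <- 0
  counts[1:3, "G10"] <- 5   # detected in only 3 cells
  out <- qc_filter(counts, min_umis = 0, min_genes = 0,
                   min_cells_per_gene = 25)
  expect_false("G10" %in% colnames(out$counts))
  expect_identical(unname(out$report[["genes_removed"]]), 1L)
  expect_true(all(paste0("G", 1:9) %in% colnames(out$counts)))
})

test_that("normalisation rescales cells and excludes dominant genes from the size factor", {
  # no gene above 5%: [10, 90, ...] scales so the counted total is 10000
  counts <- matrix(rep(c(10, 90), 25), 1, 50,
                   dimnames = list("c1", paste0("G", 1:50)))
  norm <- normalize_counts(counts, scale_factor = 10000)
  expect_equal(unname(rowSums(norm)), 10000)
  expect_equal(norm[1, 1], 10 / (2500 / 10000))
  # a dominant gene (50% of the cell) is excluded from the size factor
  # but still divided by it
  v <- c(1000, rep(25, 40))
  counts2 <- matrix(v, 1, 41,
                    dimnames = list("c1", paste0("G", 1:41)))
  norm2 <- normalize_counts(counts2, scale_factor = 10000)
  sf <- 1000 / 10000   # counted total excludes the dominant gene
  expect_equal(unname(norm2[1, 1]), 1000 / sf)
  expect_equal(unname(norm2[1, 2]), 25 / sf)
  expect_identical(attr(norm2, "steps"), "normalized")
  # uniform rows: every cell ends at the same counted total
  u <- matrix(rpois(200, 50) + 1, 4, 50,
              dimnames = list(paste0("c", 1:4), paste0("G", 1:50)))
  nu <- normalize_counts(u)
  expect_equal(unname(rowSums(nu)), rep(10000, 4), tolerance = 1e-9)
})

test_that("log transform is ln(1+x), recorded once", {
  m <- matrix(c(0, exp(1) - 1), 1, 2,
              dimnames = list("c", c("a", "b")))
  attr(m, "steps") <- "normalized"
  lg <- log_transform(m)
  expect_equal(unname(lg[1, ]), c(0, 1))
  expect_identical(attr(lg, "steps"), c("normalized", "log1p"))
  expect_error(log_transform(lg), "state error")
})

test_that("program scoring is seeded-deterministic and direction-correct", {
  set.seed(97)
  n_cells <- 300; n_genes <- 400
  base <- matrix(rlnorm(n_cells * n_genes, 0, 0.3), n_cells, n_genes,
                 dimnames = list(NULL, paste0("G", 1:n_genes)))
  prog <- paste0("G", 1:8)
  hot <- 1:150  # first half of cells express the program
  base[hot, prog] <- base[hot, prog] * 4
  sc1 <- score_gene_program(base, prog)
  sc2 <- score_gene_program(base, prog)
  expect_identical(sc1, sc2)
  expect_gt(mean(sc1[hot]), mean(sc1[-hot]) + 0.2)
  # scale invariance of the sign: adding a constant to all genes cancels
  shifted <- base + 2
  sc3 <- score_gene_program(shifted, prog)
  expect_equal(stats::cor(sc1, sc3), 1, tolerance = 0.05)
  expect_warning(score_gene_program(base, c(prog, "ghost")), "absent")
  expect_error(suppressWarnings(score_gene_program(base, "ghost")),
               "value error")
})

test_that("stem index is revCSC minus proCSC with aligned cells", {
  expect_equal(stem_cell_index(c(a = 0.2), c(a = 0.5)), c(a = 0.3))
  expect_equal(unname(stem_cell_index(c(1, 2), c(0, 0))), c(-1, -2))
  expect_error(stem_cell_index(1:3, 1:2), "length")
  expect_error(stem_cell_index(c(a = 1), c(b = 1)), "mismatch")
  s <- stem_index_summary(c(1, 2, 3, 10), sample = c("x", "x", "x", "y"))
  expect_identical(s$sample, c("x", "y"))
  expect_equal(s$median[1], 2)
  expect_identical(s$n, c(3L, 1L))
})

test_that("the full scoring chain orders planted program mixtures correctly", {
  cfg <- scrna_sim_config(
    n_cells = 900,
    program_mix = rep(c(0, 0.5, 1), each = 300),
    seed = 3)
  sim <- generate_scrna_counts(cfg)
  qc <- qc_filter(sim$counts, sim$metadata)
  lg <- log_transform(normalize_counts(qc$counts))
  mix <- sim$truth$program_mix[rownames(sim$counts) %in% rownames(qc$counts)]
  pro <- score_gene_program(lg, cfg$proCSC_genes)
  rev <- score_gene_program(lg, cfg$revCSC_genes)
  idx <- stem_cell_index(pro, rev)
  med <- vapply(split(idx, mix), stats::median, numeric(1))
  expect_true(all(diff(med) > 0))  # higher revCSC mix -> higher index
  # index correlates strongly with the planted mix
  expect_gt(stats::cor(idx, mix, method = "spearman"), 0.8)
})

test_that("gene-count matrices round-trip through MTX on disk", {
  cfg <- scrna_sim_config(n_cells = 40, n_genes = 120, seed = 7)
  sim <- generate_scrna_counts(cfg)
  dir <- withr::local_tempdir()
  write_gene_counts(sim, dir)
  back <- read_gene_counts(dir)
  expect_equal(as.matrix(back$counts), as.matrix(sim$counts))
  expect_identical(colnames(back$counts), colnames(sim$counts))
  expect_equal(back$metadata$umi_read_ratio, sim$metadata$umi_read_ratio,
               tolerance = 1e-9)
})
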