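test_that("scheme enumeration matches combinatorics", {
  expect_length(enumerate_scheme(9, 4)$codes, 126)
  expect_length(enumerate_scheme(3, 1)$codes, 3)
  # oracle: brute-force count of distinct 3-subsets of 6 channels
  brute <- 0
  for (a in 1:4) for (b in (a + 1):5) for (cc in (b + 1):6) brute <- brute + 1
  expect_length(enumerate_scheme(6, 3)$codes, brute)
  sch <- enumerate_scheme(4, 2)
  expect_false(anyDuplicated(sch$code_ids) > 0)
  expect_error(enumerate_scheme(4, 4), "configuration error")
  expect_error(enumerate_scheme(4, 0), "configuration error")
  expect_error(enumerate_scheme(3, 2, conditions = paste0("c", 1:5)),
               "more conditions")
})

test_that("constructed singlets are assigned and doublet-like cells rejected", {
  # 200 background cells spread each channel's intensity range, plus one
  # clean singlet on code {1,3,5,7} and one 8-bright doublet profile
  set.seed(3)
  n_bg <- 200
  codes <- enumerate_scheme(9, 4)
  pick <- sample(length(codes$codes), n_bg, replace = TRUE)
  B <- matrix(0.05 + rnorm(n_bg * 9, 0, 0.01), n_bg, 9)
  for (i in seq_len(n_bg)) B[i, codes$codes[[pick[i]]]] <- 0.9 +
      rnorm(4, 0, 0.01)
  singlet <- rep(0.05, 9); singlet[c(1, 3, 5, 7)] <- 0.9
  doublet <- rep(0.9, 9); doublet[9] <- 0.05
  vals <- rbind(B, singlet, doublet)
  colnames(vals) <- paste0("BC", 1:9)
  roles <- c(stats::setNames(rep("barcode", 9), colnames(vals)),
             DNA1 = "DNA", cisplatin = "viability")
  vals <- cbind(vals, DNA1 = 5, cisplatin = 0.5)
  tb <- cell_table(vals, roles, transform = "arcsinh")
  calls <- debarcode(tb, codes, separation_threshold = 0.3)
  i_s <- n_bg + 1; i_d <- n_bg + 2
  expect_true(calls$assigned[i_s])
  expect_identical(calls$code[i_s], "1.3.5.7")
  expect_gt(calls$separation[i_s], 0.7)
  expect_false(calls$assigned[i_d])
  expect_lt(calls$separation[i_d], 0.1)
})

test_that("raw tables are refused and channel counts checked", {
  cfg <- cytometry_sim_config("a", 50, seed = 2)
  sim <- generate_cytometry_experiment(cfg)
  expect_error(debarcode(sim$table, cfg$barcode_scheme), "state error")
  sch6 <- enumerate_scheme(6, 3)
  expect_error(debarcode(arcsinh_transform(sim$table), sch6),
               "barcode channels")
})

test_that("synthetic pool at doublet rate 0 is 100% correctly assigned", {
  # all 126 codes in use, so every barcode channel carries both states
  pool <- pooled_pool(126, 40, doublet_rate = 0, seed = 37)
  calls <- debarcode(pool$table, pool$scheme, 0.3)
  expect_true(all(calls$assigned))
  expect_identical(calls$code, pool$truth$cells$true_code)
})

test_that("raising the separation threshold never increases assignments", {
  pool <- pooled_pool(126, 20, doublet_rate = 0.1, seed = 41)
  counts <- vapply(c(0, 0.2, 0.4, 0.6, 0.9), function(th)
    sum(debarcode(pool$table, pool$scheme, th)$assigned), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("split_by_condition partitions the pool and reports QC", {
  pool <- pooled_pool(126, 30, doublet_rate = 0.08, seed = 43)
  calls <- debarcode(pool$table, pool$scheme, 0.3)
  out <- split_by_condition(pool$table, calls, pool$scheme)
  n_split <- sum(vapply(out$tables, n_cells, numeric(1)))
  expect_equal(n_split + attr(out$qc, "n_unassigned"),
               n_cells(pool$table))
  # per-condition counts near the planted allocation (30 singlets each,
  # plus at most a handful of falsely assigned doublets)
  for (cd in paste0("c", 1:126)) {
    n_cd <- if (cd %in% names(out$tables)) n_cells(out$tables[[cd]]) else 0
    expect_lt(abs(n_cd - 30), 10)
  }
  expect_true(all(out$qc$n_assigned > 0))
})

test_that("degenerate splits work: tiny pools and zero assignments", {
  # all 6 codes of the 4-choose-2 scheme mapped; cells use "1.2" (-> x)
  # and "3.4" (-> v) so every channel carries both hot and cold states
  sch <- enumerate_scheme(4, 2, conditions = c("x", "y", "z", "w", "u", "v"))
  vals <- matrix(0.05, 5, 4, dimnames = list(NULL, paste0("BC", 1:4)))
  vals[1:3, c(1, 2)] <- 0.9   # code "1.2" -> x
  vals[4:5, c(3, 4)] <- 0.9   # code "3.4" -> v
  roles <- c(stats::setNames(rep("barcode", 4), paste0("BC", 1:4)),
             DNA1 = "DNA", cisplatin = "viability")
  tb <- cell_table(cbind(vals, DNA1 = 5, cisplatin = 0.1), roles,
                   transform = "arcsinh")
  calls <- debarcode(tb, sch, 0.3)
  out <- split_by_condition(tb, calls, sch)
  expect_identical(n_cells(out$tables$x), 3L)
  expect_identical(n_cells(out$tables$v), 2L)
  none <- calls; none$assigned[] <- FALSE; none$code[] <- NA
  out0 <- split_by_condition(tb, none, sch)
  expect_length(out0$tables, 0)
  expect_identical(attr(out0$qc, "n_unassigned"), 5L)
})
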