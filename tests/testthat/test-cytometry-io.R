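test_that("CSV round-trip preserves events, channels and metadata", {
  vals <- matrix(c(1.5, 0, 3.25, 10, 200.5, 0.125), 3, 2,
                 dimnames = list(NULL, c("DNA1", "cisplatin")))
  tb <- cell_table(vals, c(DNA1 = "DNA", cisplatin = "viability"),
                   condition = c("a", "a", "b"), batch = "b1")
  expect_equal(n_cells(tb), 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(tb, path)
  back <- read_cell_table(path, paste0(path, ".manifest.yaml"))
  expect_equal(back$values, tb$values, tolerance = 1e-6)
  expect_identical(back$cells$condition, tb$cells$condition)
  expect_identical(back$channel_roles, tb$channel_roles)
})

test_that("unknown channels get role 'other'; missing manifest errors", {
  vals <- matrix(1:4, 2, 2, dimnames = list(NULL, c("DNA1", "mystery")))
  tb <- cell_table(vals, c(DNA1 = "DNA"))
  expect_identical(unname(tb$channel_roles[["mystery"]]), "other")
  path <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(tb, path)
  expect_error(read_cell_table(path, list(no_channels = TRUE)),
               "manifest error")
  expect_error(read_cell_table(path, "/nonexistent/manifest.yaml"),
               "not found")
})

test_that("arcsinh transform matches the closed form and is monotone", {
  vals <- matrix(c(0, 5, 1, 7), 2, 2,
                 dimnames = list(NULL, c("DNA1", "cisplatin")))
  tb <- cell_table(vals, c(DNA1 = "DNA", cisplatin = "viability"))
  tr <- arcsinh_transform(tb, cofactor = 5)
  expect_identical(unname(tr$values[1, "DNA1"]), 0)
  expect_equal(unname(tr$values[2, "DNA1"]), log(1 + sqrt(2)))
  # monotonicity: increasing raw values stay increasing after transform
  x <- sort(runif(200, 0, 500))
  tb2 <- make_table(cbind(m = x))
  tr2 <- arcsinh_transform(tb2, cofactor = 3)
  expect_true(all(diff(tr2$values[, "m"]) > 0))
  # double transform is a state error
  expect_error(arcsinh_transform(tr), "state error")
})

test_that("batch centering zeroes per-batch means and removes planted offsets", {
  vals <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "m"))
  tb <- cell_table(vals, c(m = "PTM"), transform = "arcsinh")
  ct <- batch_mean_center(tb)
  expect_equal(unname(ct$values[, 1]), c(-1, 0, 1))

  set.seed(42)
  base <- rnorm(400)
  offset <- 1.7
  vals <- matrix(c(base, base + offset), ncol = 1,
                 dimnames = list(NULL, "m"))
  tb <- cell_table(vals, c(m = "PTM"),
                   batch = rep(c("b1", "b2"), each = 400),
                   transform = "arcsinh")
  ct <- batch_mean_center(tb)
  m1 <- mean(ct$values[tb$cells$batch == "b1", 1])
  m2 <- mean(ct$values[tb$cells$batch == "b2", 1])
  expect_lt(abs(m1), 1e-9)
  expect_lt(abs(m2), 1e-9)
  expect_lt(abs(m1 - m2), 1e-9)
  # identical batches give identical output blocks
  vals2 <- matrix(rep(base, 2), ncol = 1, dimnames = list(NULL, "m"))
  tb2 <- cell_table(vals2, c(m = "PTM"),
                    batch = rep(c("b1", "b2"), each = 400),
                    transform = "arcsinh")
  ct2 <- batch_mean_center(tb2)
  expect_equal(ct2$values[1:400, ], ct2$values[401:800, ])
  # raw tables must be transformed first; double centering is an error
  expect_error(batch_mean_center(cell_table(
    matrix(1, 1, 1, dimnames = list(NULL, "m")), c(m = "PTM"))),
    "state error")
  expect_error(batch_mean_center(ct), "state error")
})

test_that("arcsinh + centering commutes with cell permutation", {
  set.seed(7)
  vals <- matrix(rexp(300), 100, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  tb <- cell_table(vals, stats::setNames(rep("PTM", 3), c("a", "b", "c")),
                   batch = sample(c("b1", "b2"), 100, TRUE))
  perm <- sample(100)
  out1 <- batch_mean_center(arcsinh_transform(tb))
  out2 <- batch_mean_center(arcsinh_transform(subset_cells(tb, perm)))
  expect_equal(out2$values, out1$values[perm, ])
})

test_that("threshold gating follows the positive/negative semantics", {
  vals <- matrix(c(3, 0.1, 0.1, 0.1, 0, 4), 3, 2, byrow = FALSE,
                 dimnames = list(NULL, c("PanCK", "CD45")))
  vals <- cbind(vals, EpCAM = c(3, 0.1, 0.5))
  roles <- c(PanCK = "lineage", CD45 = "lineage", EpCAM = "lineage")
  tb <- cell_table(vals, roles, transform = "arcsinh")
  epi <- gate_spec("epithelial", positive = c(PanCK = 1, EpCAM = 1))
  gd <- gate_spec("gd_t", positive = c(CD45 = 1),
                  negative = c(PanCK = 1))
  tb <- gate_population(tb, epi)
  tb <- gate_population(tb, gd)
  expect_identical(tb$cells$assigned_population,
                   c("epithelial", "unassigned", "gd_t"))
  # cell with CD45 = 0 against a CD45+ requirement is not gd_t
  expect_false(tb$cells$assigned_population[1] == "gd_t")
  # idempotent
  again <- gate_population(gate_population(tb, epi), gd)
  expect_identical(again$cells$assigned_population,
                   tb$cells$assigned_population)
  # boundary: value equal to a positive threshold is NOT positive
  at <- cell_table(matrix(1, 1, 3, dimnames = list(NULL, names(roles))),
                   roles, transform = "arcsinh")
  at <- gate_population(at, epi)
  expect_identical(at$cells$assigned_population, "unassigned")
  expect_error(gate_spec("x", positive = c(a = 1), negative = c(a = 0)),
               "cannot be both")
  expect_error(gate_spec("x", positive = c(a = Inf)), "finite")
})

test_that("gated fractions recover planted mixture weights within 2%", {
  cfg <- cytometry_sim_config(
    "mix", 5000,
    population_mix = list(mix = c(gd_t = 0.6, epithelial = 0.4)),
    seed = 21)
  sim <- generate_cytometry_experiment(cfg)
  tb <- arcsinh_transform(sim$table)
  tb <- gate_population(tb, gate_spec("epithelial",
                                      positive = c(PanCK = 2.5, EpCAM = 2.5)))
  tb <- gate_population(tb, gate_spec("gd_t",
                                      positive = c(CD45 = 2.5, CD3 = 2.5,
                                                   gdTCR = 2.5)))
  frac_gd <- mean(tb$cells$assigned_population == "gd_t")
  frac_epi <- mean(tb$cells$assigned_population == "epithelial")
  expect_lt(abs(frac_gd - 0.6), 0.02)
  expect_lt(abs(frac_epi - 0.4), 0.02)
  # disjoint gates never double-label (partition-safe by construction):
  # population labels are single-valued and every cell has exactly one
  expect_true(all(tb$cells$assigned_population %in%
                    c("gd_t", "epithelial", "unassigned")))
})
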