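test_that("signed EMD matches hand-computed examples", {
  expect_equal(signed_emd(c(1, 1, 2, 2), c(0, 0, 1, 1)), 1)
  expect_equal(signed_emd(c(0, 0, 1, 1), c(1, 1, 2, 2)), -1)
  expect_equal(signed_emd(c(5, 5, 5), c(5, 5, 5)), 0)
  # equal-size: mean |sorted difference|
  expect_equal(signed_emd(c(0, 10), c(1, 3)), (1 + 7) / 2)
  # unequal sizes: {0} vs {0,1} has |F diff| = 1/2 on [0,1]
  expect_equal(abs(signed_emd(0, c(0, 1))), 0.5)
  expect_error(signed_emd(numeric(0), 1), "value error")
  expect_error(signed_emd(c(1, NA), 1), "NA")
})

test_that("signed EMD agrees with the sorted-sample oracle over 200 random instances", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(2:60, 1)
    x <- rnorm(n, sd = runif(1, 0.2, 3))
    y <- rnorm(n, mean = runif(1, -2, 2))
    oracle <- mean(abs(sort(x) - sort(y)))
    expect_equal(abs(signed_emd(x, y)), oracle, tolerance = 1e-12)
  }
})

test_that("unequal-size EMD equals the replicate-to-LCM oracle", {
  set.seed(103)
  for (i in 1:25) {
    nx <- sample(2:12, 1); ny <- sample(2:12, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    L <- nx * ny  # common multiple
    oracle <- mean(abs(sort(rep(x, each = L / nx)) -
                       sort(rep(y, each = L / ny))))
    expect_equal(abs(signed_emd(x, y)), oracle, tolerance = 1e-12)
  }
})

test_that("signed EMD respects translation, symmetry and scaling", {
  set.seed(107)
  x <- rexp(400); y <- rexp(300) * 1.5
  e <- signed_emd(x, y)
  expect_equal(signed_emd(y, x), -e)
  expect_equal(signed_emd(x + 2, x), 2)
  expect_equal(signed_emd(x - 0.75, x), -0.75)
  expect_equal(abs(signed_emd(3 * x, 3 * y)), 3 * abs(e))
  expect_equal(signed_emd(x, x), 0)
  # triangle inequality in magnitude
  z <- rnorm(250)
  expect_lte(abs(signed_emd(x, z)),
             abs(signed_emd(x, y)) + abs(signed_emd(y, z)) + 1e-12)
})

test_that("compute_shifts excludes barcode/DNA/viability and averages correctly", {
  set.seed(109)
  roles <- c(BC1 = "barcode", DNA1 = "DNA", cisplatin = "viability",
             pSTAT3 = "PTM", pERK = "PTM", PanCK = "lineage")
  mk <- function(shift3, shiftE) {
    v <- cbind(BC1 = rnorm(500), DNA1 = rnorm(500), cisplatin = rnorm(500),
               pSTAT3 = rnorm(500) + shift3, pERK = rnorm(500) + shiftE,
               PanCK = rnorm(500))
    cell_table(v, roles, transform = "centered")
  }
  ref <- mk(0, 0); tst <- mk(1, -0.5)
  res <- compute_shifts(tst, ref, condition = "c", reference_id = "r")
  expect_setequal(res$markers$marker, c("pSTAT3", "pERK", "PanCK"))
  expect_equal(res$xbar_emd, mean(res$markers$abs_emd))
  expect_equal(xbar_emd(res), res$xbar_emd)
  expect_equal(xbar_emd(c(-1, 3)), 2)
  e3 <- res$markers$signed_emd[res$markers$marker == "pSTAT3"]
  eE <- res$markers$signed_emd[res$markers$marker == "pERK"]
  expect_gt(e3, 0.8); expect_lt(eE, -0.3)
  expect_error(compute_shifts(tst, ref, markers = "ghost"), "missing")
  expect_error(compute_shifts(arcsinh_transform(make_table(
    matrix(1:4, 2, 2))), ref), "transform states")
})

test_that("fraction_positive uses a strict threshold", {
  expect_equal(fraction_positive(c(0, 1, 2, 3), 1), 0.5)
  expect_equal(fraction_positive(c(1, 1, 1), 1), 0)
  expect_equal(fraction_positive(c(2, 3), 1), 1)
  expect_error(fraction_positive(numeric(0), 0), "value error")
})

test_that("therapeutic apoptosis reports percentage-point differences", {
  mk <- function(frac, n = 2000) {
    v <- cbind(cPARP = c(rep(3, round(frac * n)),
                         rep(-1, n - round(frac * n))))
    cell_table(v, c(cPARP = "state"), transform = "centered")
  }
  expect_equal(therapeutic_apoptosis(mk(0.45), mk(0.10)), 35)
  expect_equal(therapeutic_apoptosis(mk(0.10), mk(0.10)), 0)
  expect_equal(therapeutic_apoptosis(mk(0.60), mk(0.10)), 50)
  # protection shows up as a negative value
  expect_equal(therapeutic_apoptosis(mk(0.05), mk(0.25)), -20)
  empty <- subset_cells(mk(0.5), integer(0))
  expect_error(therapeutic_apoptosis(empty, mk(0.1)), "empty gated")
})

test_that("cell-state classification follows the priority hierarchy", {
  v <- rbind(
    c(cPARP = 5, IdU = 5, pRB = 5),   # apoptotic wins over S
    c(cPARP = -1, IdU = 5, pRB = -1), # S wins over G0
    c(cPARP = -1, IdU = -1, pRB = -1),# pRB-negative -> G0
    c(cPARP = -1, IdU = -1, pRB = 5), # other
    c(cPARP = 0, IdU = 0, pRB = 0))   # at-threshold: not positive -> G0
  roles <- c(cPARP = "state", IdU = "state", pRB = "state")
  tb <- cell_table(v, roles, transform = "centered")
  st <- classify_cell_state(tb)
  expect_identical(st, c("apoptotic", "S", "G0", "other", "G0"))
  cnt <- cell_state_counts(tb)
  expect_identical(sum(cnt), 5L)
  expect_identical(unname(cnt[c("apoptotic", "S", "G0", "other")]),
                   c(1L, 1L, 2L, 1L))
  expect_error(classify_cell_state(make_table(cbind(a = 1))),
               "configuration error")
})

test_that("planted state fractions are recovered within 2 points", {
  cfg <- cytometry_sim_config("a", 4000, apoptosis_fraction = c(a = 0.25),
                              s_phase_fraction = c(a = 0.2), seed = 47)
  sim <- generate_cytometry_experiment(cfg)
  tb <- arcsinh_transform(sim$table)
  cnt <- cell_state_counts(tb, thresholds = c(cPARP = 2.5, IdU = 2.5,
                                              pRB = 2))
  n <- sum(cnt)
  expect_lt(abs(cnt[["apoptotic"]] / n - 0.25), 0.02)
  expect_lt(abs(cnt[["S"]] / n - 0.20), 0.02)
})

test_that("percent change in positivity handles the zero-control case", {
  mk <- function(pos, neg) make_table(
    cbind(TIGIT = c(rep(2, pos), rep(-2, neg))),
    c(TIGIT = "immunophenotype"), transform = "centered")
  expect_equal(percent_change_positive(mk(3, 1), mk(2, 2), "TIGIT"), 50)
  expect_equal(percent_change_positive(mk(1, 3), mk(4, 0), "TIGIT"), -75)
  expect_warning(out <- percent_change_positive(mk(1, 1), mk(0, 2), "TIGIT"),
                 "undefined")
  expect_true(is.na(out))
})

test_that("kendall tau matches hand-worked values", {
  expect_equal(kendall_tau(1:5, 2 * (1:5)), 1)
  expect_equal(kendall_tau(1:5, -(1:5)), -1)
  # 4 points, one discordant pair: (C - D) / total = (5 - 1) / 6
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(1, 2, 4, 3)), 4 / 6)
  expect_error(kendall_tau(1:3, 1:4), "length mismatch")
  expect_error(kendall_tau(1, 1), "at least 2")
})
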