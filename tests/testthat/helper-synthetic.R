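# shared builders for synthetic fixtures (all generated in code)

# minimal valid panel for hand-built tables
tiny_panel <- function(extra = character()) {
  c(DNA1 = "DNA", cisplatin = "viability",
    stats::setNames(rep("PTM", length(extra)), extra))
}

# a cell_table from a plain matrix of analysis channels
make_table <- function(values, roles = NULL, ...) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("ch", seq_len(ncol(values)))
  }
  if (is.null(roles)) {
    roles <- c(stats::setNames(rep("PTM", ncol(values)), colnames(values)))
  }
  cell_table(values, roles, ...)
}

# two-condition experiment with one planted shift
shifted_pair <- function(delta, n = 5000, marker = "pSTAT3", seed = 11) {
  cfg <- cytometry_sim_config(
    c("ctrl", "test"), n,
    shift_map = if (delta != 0) {
      data.frame(condition = "test", marker = marker, delta = delta)
    } else NULL,
    seed = seed)
  sim <- generate_cytometry_experiment(cfg)
  tab <- arcsinh_transform(sim$table)
  idx <- split(seq_len(n_cells(tab)), sim$truth$cells$condition)
  list(test = subset_cells(tab, idx$test),
       ctrl = subset_cells(tab, idx$ctrl),
       truth = sim$truth)
}

# single condition with one planted PTM dependency of strength s
dependency_table <- function(s, n = 5000, seed = 5,
                             x = "pSTAT3", y = "pSTAT5") {
  cfg <- cytometry_sim_config(
    "A", n,
    dependency_map = data.frame(condition = "A", x_ptm = x, y_ptm = y,
                                strength = s),
    seed = seed)
  arcsinh_transform(generate_cytometry_experiment(cfg)$table)
}

# pooled multi-code experiment for debarcoding tests
pooled_pool <- function(n_conditions, cells_per_condition, doublet_rate,
                        seed) {
  conds <- paste0("c", seq_len(n_conditions))
  cfg <- cytometry_sim_config(conds, cells_per_condition,
                              doublet_rate = doublet_rate, seed = seed)
  sim <- generate_cytometry_experiment(cfg)
  list(table = arcsinh_transform(sim$table), truth = sim$truth,
       scheme = cfg$barcode_scheme)
}
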