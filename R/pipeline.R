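#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: the pooled input CSV and
#' channel manifest, the barcode scheme and its condition mapping, gate
#' specs, state thresholds, the control reference of every test
#' condition for the shift and delta-DREMI stages, the apoptosis
#' baselines of co-cultures, estimator settings and seeds. The config
#' round-trips losslessly through YAML.
#'
#' @param input_csv pooled event CSV (see [write_cell_table()]).
#' @param manifest channel manifest path or list.
#' @param scheme_conditions condition ids in barcode-code order.
#' @param n_barcode_channels,k_hot barcode scheme shape.
#' @param separation_threshold debarcoder threshold.
#' @param cofactor arcsinh cofactor.
#' @param gates list of [gate_spec()] argument lists
#'   (`population`, `positive`, `negative`).
#' @param state_thresholds named vector (`cPARP`, `IdU`, `pRB`) of
#'   positivity cutoffs on the arcsinh scale.
#' @param shift_control named map test condition -> control condition
#'   (gd_t population shift stage).
#' @param apoptosis_baseline named map co-culture condition -> organoid
#'   monoculture condition (epithelial therapeutic-apoptosis stage).
#' @param dremi_panel PTM channel names for the DREMI stage.
#' @param dremi_control named map condition -> control for delta-DREMI
#'   (defaults to `shift_control`).
#' @param dremi_settings list(k, n_bins, n_mesh).
#' @param embed_settings list(k, alpha, t, seed).
#' @param shift_markers optional marker inclusion override for the shift
#'   stage.
#' @param seed master seed recorded in the manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_csv, manifest, scheme_conditions,
                            n_barcode_channels = 9, k_hot = 4,
                            separation_threshold = 0.3, cofactor = 5,
                            gates = list(
                              list(population = "epithelial",
                                   positive = c(PanCK = 2.5, EpCAM = 2.5)),
                              list(population = "gd_t",
                                   positive = c(CD45 = 2.5, CD3 = 2.5,
                                                gdTCR = 2.5))),
                            state_thresholds = c(cPARP = 2.5, IdU = 2.5,
                                                 pRB = 2),
                            shift_control = character(),
                            apoptosis_baseline = character(),
                            dremi_panel = default_ptm_panel(),
                            dremi_control = NULL,
                            dremi_settings = list(k = 10, n_bins = 20,
                                                  n_mesh = 3),
                            embed_settings = list(k = 5, alpha = 10,
                                                  t = 10, seed = 42),
                            shift_markers = NULL,
                            seed = 1L) {
  if (is.null(dremi_control)) dremi_control <- shift_control
  cfg <- structure(list(
    input_csv = input_csv, manifest = manifest,
    scheme_conditions = scheme_conditions,
    n_barcode_channels = n_barcode_channels, k_hot = k_hot,
    separation_threshold = separation_threshold, cofactor = cofactor,
    gates = gates, state_thresholds = state_thresholds,
    shift_control = shift_control,
    apoptosis_baseline = apoptosis_baseline,
    dremi_panel = dremi_panel, dremi_control = dremi_control,
    dremi_settings = dremi_settings, embed_settings = embed_settings,
    shift_markers = shift_markers, seed = as.integer(seed)
  ), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration before any stage runs
#'
#' Checks the control mappings: every mapped condition and control must
#' exist in the scheme's condition list, and each test condition must
#' declare exactly one control. Errors abort before stage execution.
#'
#' @param config a `pipeline_config`.
#' @return the config, invisibly.
#' @export
validate_pipeline_config <- function(config) {
  conds <- config$scheme_conditions
  for (map_name in c("shift_control", "dremi_control",
                     "apoptosis_baseline")) {
    map <- config[[map_name]]
    if (!length(map)) next
    if (is.null(names(map)) || anyDuplicated(names(map))) {
      stop("config error: ", map_name,
           " must map each condition to exactly one control")
    }
    bad <- setdiff(c(names(map), unname(map)), conds)
    if (length(bad)) {
      stop("config error: ", map_name, " references unknown condition(s): ",
           paste(bad, collapse = ", "))
    }
  }
  invisible(config)
}

#' Write / read a pipeline config as YAML
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @return `path` (write) or the restored `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$gates <- lapply(x$gates, function(g) {
    lapply(g, function(e) if (is.numeric(e)) as.list(e) else e)
  })
  for (nm in c("state_thresholds", "shift_control", "apoptosis_baseline",
               "dremi_control")) {
    x[[nm]] <- as.list(x[[nm]])
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$gates <- lapply(x$gates, function(g) {
    g$positive <- unlist(g$positive); g$negative <- unlist(g$negative)
    g
  })
  for (nm in c("state_thresholds", "shift_control", "apoptosis_baseline",
               "dremi_control")) {
    x[[nm]] <- unlist(x[[nm]])
    if (is.null(x[[nm]])) x[[nm]] <- character(0)
  }
  do.call(pipeline_config, x)
}

# small deterministic content hash for provenance manifests
.settings_hash <- function(obj) {
  s <- paste(deparse(obj), collapse = "\n")
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full condition-screen pipeline
#'
#' Stages: read the pooled table, arcsinh-transform, debarcode and split
#' by condition, gate populations and measure cell-state fractions on the
#' arcsinh scale, batch mean-centre, compute per-condition signed-EMD
#' shift profiles and x-bar EMD against the declared controls, compute
#' DREMI tables and delta-DREMI vectors, and embed the condition-level
#' signed-EMD matrix (PCA and diffusion potential). Each stage writes a
#' plain TSV under `out_dir`; a YAML run manifest records the settings
#' hash and seeds. Re-running with an identical config reproduces
#' identical outputs.
#'
#' @param config a [pipeline_config()] (or path to its YAML).
#' @param out_dir output directory, created if needed.
#' @param stages subset of
#'   `c("debarcode", "gate", "shift", "dremi", "embed")` to run (later
#'   stages need the earlier ones within the same call; default all).
#' @return invisibly, a list with the per-condition tables, the summary
#'   table, the long shift table and the paths of the stage outputs.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("debarcode", "gate", "shift",
                                    "dremi", "embed")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  unlink(log_path)
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  outputs <- list()

  logf("stage read: %s", config$input_csv)
  pooled <- read_cell_table(config$input_csv, config$manifest)
  pooled <- arcsinh_transform(pooled, config$cofactor)

  scheme <- enumerate_scheme(config$n_barcode_channels, config$k_hot,
                             conditions = config$scheme_conditions)
  logf("stage debarcode: %d cells, %d codes", n_cells(pooled),
       length(scheme$codes))
  calls <- debarcode(pooled, scheme, config$separation_threshold)
  split <- split_by_condition(pooled, calls, scheme)
  qc_path <- file.path(out_dir, "debarcode_qc.tsv")
  utils::write.table(split$qc, qc_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  outputs$debarcode_qc <- qc_path
  logf("  assigned %d / %d cells", sum(calls$assigned), nrow(calls))
  if (!"gate" %in% stages) {
    return(invisible(list(tables = split$tables, outputs = outputs)))
  }

  logf("stage gate: %d gates", length(config$gates))
  tables <- lapply(split$tables, function(tb) {
    for (g in config$gates) tb <- gate_population(tb, do.call(gate_spec, g))
    tb
  })

  # cell-state metrics on the arcsinh (pre-centering) scale
  st <- config$state_thresholds
  states <- do.call(rbind, lapply(names(tables), function(cd) {
    tb <- tables[[cd]]
    gd <- gated_population(tb, "gd_t")
    epi <- gated_population(tb, "epithelial")
    row <- data.frame(condition = cd, n_cells = n_cells(tb),
                      n_gd = n_cells(gd), n_epithelial = n_cells(epi),
                      stringsAsFactors = FALSE)
    for (pop in c("gd", "epithelial")) {
      p <- if (pop == "gd") gd else epi
      row[[paste0(pop, "_apoptotic_frac")]] <- if (n_cells(p))
        fraction_positive(p$values[, "cPARP"], st[["cPARP"]]) else NA_real_
      row[[paste0(pop, "_s_phase_frac")]] <- if (n_cells(p))
        fraction_positive(p$values[, "IdU"], st[["IdU"]]) else NA_real_
    }
    row
  }))
  states$therapeutic_apoptosis <- NA_real_
  for (cd in names(config$apoptosis_baseline)) {
    base_cd <- config$apoptosis_baseline[[cd]]
    if (!cd %in% names(tables) || !base_cd %in% names(tables)) next
    co <- gated_population(tables[[cd]], "epithelial")
    mono <- gated_population(tables[[base_cd]], "epithelial")
    if (!n_cells(co) || !n_cells(mono)) {
      stop("stage gate: empty epithelial gate for sample ", cd)
    }
    states$therapeutic_apoptosis[states$condition == cd] <-
      therapeutic_apoptosis(co, mono, threshold = st[["cPARP"]])
  }

  # batch mean-centering for distribution comparisons
  all_tb <- batch_mean_center(bind_cell_tables(tables))
  centered <- lapply(split(seq_len(n_cells(all_tb)),
                           all_tb$cells$condition),
                     function(i) subset_cells(all_tb, i))

  shifts_long <- NULL
  if ("shift" %in% stages && length(config$shift_control)) {
    logf("stage shift: %d conditions", length(config$shift_control))
    shift_rows <- list(); xbar_rows <- list()
    for (cd in names(config$shift_control)) {
      ctrl <- config$shift_control[[cd]]
      test <- gated_population(centered[[cd]], "gd_t")
      ref <- gated_population(centered[[ctrl]], "gd_t")
      if (!n_cells(test) || !n_cells(ref)) {
        stop("stage shift: empty gd_t gate for sample ", cd)
      }
      sh <- compute_shifts(test, ref, markers = config$shift_markers,
                           condition = cd, reference_id = ctrl)
      shift_rows[[cd]] <- data.frame(condition = cd, reference = ctrl,
                                     sh$markers,
                                     stringsAsFactors = FALSE)
      xbar_rows[[cd]] <- data.frame(condition = cd, reference = ctrl,
                                    xbar_emd = sh$xbar_emd,
                                    stringsAsFactors = FALSE)
    }
    shifts_long <- do.call(rbind, shift_rows)
    rownames(shifts_long) <- NULL
    shifts_path <- file.path(out_dir, "shifts.tsv")
    utils::write.table(shifts_long, shifts_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    outputs$shifts <- shifts_path
    states <- merge(states, do.call(rbind, xbar_rows),
                    by = "condition", all.x = TRUE, sort = TRUE)
  }
  summary_path <- file.path(out_dir, "summary.tsv")
  utils::write.table(states, summary_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  outputs$summary <- summary_path

  if ("dremi" %in% stages && length(config$dremi_control)) {
    logf("stage dremi: panel of %d PTMs", length(config$dremi_panel))
    ds <- config$dremi_settings
    need <- unique(c(names(config$dremi_control),
                     unname(config$dremi_control)))
    dtabs <- lapply(stats::setNames(need, need), function(cd) {
      gd <- gated_population(centered[[cd]], "gd_t")
      if (n_cells(gd) < ds$k + 1) {
        stop("stage dremi: too few gd_t cells in sample ", cd)
      }
      dremi_table(gd, panel = config$dremi_panel,
                  k = ds$k, n_bins = ds$n_bins, n_mesh = ds$n_mesh)
    })
    dremi_long <- do.call(rbind, lapply(need, function(cd) {
      data.frame(condition = cd, dtabs[[cd]]$scores,
                 stringsAsFactors = FALSE)
    }))
    dremi_path <- file.path(out_dir, "dremi.tsv")
    utils::write.table(dremi_long, dremi_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    outputs$dremi <- dremi_path
    deltas <- lapply(names(config$dremi_control), function(cd) {
      dd <- delta_dremi(dtabs[[cd]], dtabs[[config$dremi_control[[cd]]]])
      stats::setNames(dd$delta_dremi,
                      paste(dd$x_ptm, dd$y_ptm, sep = "->"))
    })
    delta_wide <- do.call(rbind, deltas)
    rownames(delta_wide) <- names(config$dremi_control)
    delta_path <- file.path(out_dir, "delta_dremi_wide.tsv")
    utils::write.table(cbind(condition = rownames(delta_wide),
                             as.data.frame(delta_wide)),
                       delta_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    outputs$delta_dremi <- delta_path
  }

  if ("embed" %in% stages && !is.null(shifts_long)) {
    logf("stage embed")
    cm <- condition_matrix(data.frame(condition = shifts_long$condition,
                                      feature = shifts_long$marker,
                                      value = shifts_long$signed_emd),
                           feature_kind = "signed_emd")
    es <- config$embed_settings
    for (method in c("pca", "diffusion")) {
      emb <- if (method == "pca") pca_embed(cm) else
        diffusion_potential_embed(cm, k = min(es$k, nrow(cm) - 1),
                                  alpha = es$alpha, t = es$t,
                                  seed = es$seed)
      df <- data.frame(emb, method = attr(emb, "method"),
                       settings_hash = .settings_hash(attr(emb, "settings")))
      p <- file.path(out_dir, paste0("coords_", method, ".tsv"))
      utils::write.table(df, p, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      outputs[[paste0("coords_", method)]] <- p
    }
  }

  manifest <- list(
    package = "phenoscaper",
    version = as.character(utils::packageVersion("phenoscaper")),
    seed = config$seed,
    settings_hash = .settings_hash(unclass(config)),
    stages = stages,
    outputs = lapply(outputs, basename)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  logf("run complete: %d outputs", length(outputs))
  invisible(list(tables = centered, states = states,
                 shifts = shifts_long, outputs = outputs))
}

#' Write a ready-to-run synthetic demo experiment
#'
#' Lays down a small screen — 2 donors x 2 engineering states, immune
#' monocultures, 3 organoids as monoculture apoptosis baselines, and
#' co-cultures with each organoid with and without opsonising antibody —
#' with 1,000 cells per condition and a planted "antibody rescues
#' immunomodulation" effect: co-culture marker shifts shrink to 30% of
#' their size when the antibody flag is set, while therapeutic apoptosis
#' rises. Writes the pooled CSV, channel manifest, ground-truth YAML and
#' pipeline config into `dir`.
#'
#' @param dir output directory.
#' @param seed integer seed controlling all randomness.
#' @param cells_per_condition singlets per condition (default 1000).
#' @return list with `config` (a [pipeline_config()]), `config_path`,
#'   and `truth`.
#' @export
make_demo <- function(dir, seed = 1L, cells_per_condition = 1000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  donors <- c("D1", "D2"); engs <- c("unmod", "stIL15")
  pdos <- c("PDO1", "PDO2", "PDO3")
  design <- condition_design(donors, engs, organoids = c("none", pdos),
                             antibody = c(FALSE, TRUE), replicates = 1)
  pdo_mono <- paste0(pdos, "_mono_r1")
  conds <- c(design$condition, pdo_mono)

  pdo_weight <- c(PDO1 = 1.0, PDO2 = 0.75, PDO3 = 0.5)
  shift_template <- c(pZAP70 = 1.0, pERK = -0.8, pNFkB = -0.7,
                      GranzymeB = 0.8, TIGIT = -0.6, DNAM1 = -0.6)
  shift_rows <- list()
  apop <- stats::setNames(numeric(length(conds)), conds)
  sphase <- stats::setNames(numeric(length(conds)), conds)
  popmix <- list()
  for (i in seq_len(nrow(design))) {
    cd <- design$condition[i]
    if (design$organoid[i] == "none") {
      apop[cd] <- if (design$engineering[i] == "unmod") 0.5 else 0.05
      sphase[cd] <- if (design$engineering[i] == "unmod") 0.05 else 0.3
      popmix[[cd]] <- c(gd_t = 1)
    } else {
      w <- pdo_weight[[design$organoid[i]]] *
        (if (design$antibody[i]) 0.3 else 1)
      shift_rows[[cd]] <- data.frame(condition = cd,
                                     marker = names(shift_template),
                                     delta = unname(shift_template) * w,
                                     stringsAsFactors = FALSE)
      apop[cd] <- if (design$antibody[i]) 0.50 else 0.35
      sphase[cd] <- if (design$antibody[i]) 0.25 else 0.15
      popmix[[cd]] <- c(gd_t = 0.5, epithelial = 0.5)
    }
  }
  for (cd in pdo_mono) {
    apop[cd] <- 0.1; sphase[cd] <- 0.3
    popmix[[cd]] <- c(epithelial = 1)
  }

  batches <- stats::setNames(
    rep(c("b1", "b2"), length.out = length(conds)), conds)
  sim_cfg <- cytometry_sim_config(
    conditions = conds, cells_per_condition = cells_per_condition,
    shift_map = do.call(rbind, shift_rows),
    apoptosis_fraction = apop, s_phase_fraction = sphase,
    doublet_rate = 0.05,
    batch_effects = list(b1 = 0.15, b2 = -0.15),
    condition_batches = batches, population_mix = popmix,
    seed = seed
  )
  sim <- generate_cytometry_experiment(sim_cfg)
  csv_path <- file.path(dir, "pooled.csv")
  write_cell_table(sim$table, csv_path)
  yaml::write_yaml(list(
    seed = seed,
    apoptosis_fraction = as.list(apop),
    s_phase_fraction = as.list(sphase),
    shift_map = lapply(shift_rows, function(d)
      stats::setNames(as.list(d$delta), d$marker))
  ), file.path(dir, "ground_truth.yaml"))

  shift_control <- stats::setNames(design$control, design$condition)
  shift_control <- shift_control[!is.na(shift_control)]
  apop_base <- stats::setNames(
    paste0(design$organoid, "_mono_r1"), design$condition)
  apop_base <- apop_base[design$organoid != "none"]
  config <- pipeline_config(
    input_csv = csv_path,
    manifest = paste0(csv_path, ".manifest.yaml"),
    scheme_conditions = conds,
    shift_control = shift_control,
    apoptosis_baseline = apop_base,
    dremi_panel = default_ptm_panel()[1:6],
    seed = seed
  )
  config_path <- file.path(dir, "pipeline_config.yaml")
  write_pipeline_config(config, config_path)
  list(config = config, config_path = config_path, truth = sim$truth)
}
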