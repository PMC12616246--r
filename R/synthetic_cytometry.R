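#' Default synthetic mass-cytometry marker panel
#'
#' A panel shaped like a typical immune-organoid co-culture screen: nine
#' combinatorial barcode channels, two DNA intercalator channels, a
#' viability (cisplatin) channel, lineage channels for epithelial and
#' gamma-delta T cells, cell-state channels (cPARP apoptosis, IdU S-phase,
#' pRB proliferation), eleven phospho-PTM channels and a set of
#' immunophenotype markers.
#'
#' @return named character vector: channel name -> role.
#' @export
default_marker_panel <- function() {
  c(
    stats::setNames(rep("barcode", 9), paste0("BC", 1:9)),
    DNA1 = "DNA", DNA2 = "DNA", cisplatin = "viability",
    PanCK = "lineage", EpCAM = "lineage", CD45 = "lineage",
    CD3 = "lineage", gdTCR = "lineage",
    cPARP = "state", IdU = "state", pRB = "state",
    stats::setNames(rep("PTM", 11),
                    c("pSTAT3", "pSTAT5", "pZAP70", "pSLP76", "pNFkB",
                      "pERK", "pMAPKAPK2", "pP38", "pAKT", "pS6", "p4EBP1")),
    GranzymeB = "immunophenotype", Perforin = "immunophenotype",
    CD69 = "immunophenotype", CD16 = "immunophenotype",
    DNAM1 = "immunophenotype", TIGIT = "immunophenotype",
    NKp30 = "immunophenotype"
  )
}

#' The eleven-marker PTM panel of the default synthetic panel
#' @return character vector of 11 PTM channel names.
#' @export
default_ptm_panel <- function() {
  names(default_marker_panel())[default_marker_panel() == "PTM"]
}

#' Configuration for the synthetic cytometry experiment generator
#'
#' Describes a pooled, barcoded multi-condition experiment with planted
#' ground truth: per-(condition, marker) location shifts on the arcsinh
#' scale, per-(condition, PTM pair) sigmoidal dependencies, per-condition
#' apoptosis and S-phase fractions, a k-of-n barcode scheme, a doublet
#' rate and additive per-batch offsets.
#'
#' @param conditions character vector of condition ids (each is assigned
#'   the barcode code of the same index, in lexicographic code order).
#' @param cells_per_condition singlet cells generated per condition (>= 1).
#' @param marker_panel named character vector channel -> role; must
#'   contain at least one DNA and one viability channel.
#' @param shift_map data.frame with columns `condition`, `marker`, `delta`:
#'   planted location shift on the arcsinh scale relative to the base
#'   (control) distribution.
#' @param dependency_map data.frame with columns `condition`, `x_ptm`,
#'   `y_ptm`, `strength` (strength in \[0,1\]): planted sigmoidal
#'   dependency of `y_ptm` on `x_ptm`.
#' @param apoptosis_fraction,s_phase_fraction named numeric vectors,
#'   condition -> fraction in \[0,1\] (conditions absent default to 0.05).
#' @param g0_share fraction of the non-apoptotic, non-S remainder placed
#'   in G0 (pRB-low).
#' @param doublet_rate fraction in \[0,1\]: doublet events added as a
#'   fraction of total singlets.
#' @param barcode_scheme a [barcode_scheme()]; defaults to 9-choose-4.
#' @param batch_effects named list batch -> additive arcsinh-scale offset
#'   (scalar, or named per-marker vector).
#' @param condition_batches named character vector condition -> batch id;
#'   defaults to a single batch `"b1"`.
#' @param population_mix named list condition -> named fractions over
#'   `c("epithelial", "gd_t")`; defaults to pure gd_t.
#' @param cofactor arcsinh cofactor used when inverting to raw scale.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return a `cytometry_sim_config` list.
#' @export
cytometry_sim_config <- function(conditions,
                                 cells_per_condition,
                                 marker_panel = default_marker_panel(),
                                 shift_map = NULL,
                                 dependency_map = NULL,
                                 apoptosis_fraction = NULL,
                                 s_phase_fraction = NULL,
                                 g0_share = 0.2,
                                 doublet_rate = 0,
                                 barcode_scheme = NULL,
                                 batch_effects = NULL,
                                 condition_batches = NULL,
                                 population_mix = NULL,
                                 cofactor = 5,
                                 seed = 1L) {
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions)) stop("condition ids must be unique")
  if (cells_per_condition < 1) stop("cells_per_condition must be >= 1")
  if (doublet_rate < 0 || doublet_rate > 1) {
    stop("doublet_rate must be in [0, 1]")
  }
  if (!any(marker_panel == "DNA") || !any(marker_panel == "viability")) {
    stop("configuration error: panel must include DNA and viability channels")
  }
  if (is.null(barcode_scheme)) {
    barcode_scheme <- enumerate_scheme(9, 4, conditions = conditions)
  }
  if (length(conditions) > length(barcode_scheme$codes)) {
    stop("more conditions than barcode codes in the scheme")
  }
  frac_default <- function(x) {
    out <- stats::setNames(rep(0.05, length(conditions)), conditions)
    if (!is.null(x)) {
      if (any(x < 0 | x > 1)) stop("fractions must be in [0, 1]")
      out[names(x)] <- x
    }
    out
  }
  apoptosis_fraction <- frac_default(apoptosis_fraction)
  s_phase_fraction <- frac_default(s_phase_fraction)
  if (any(apoptosis_fraction + s_phase_fraction > 1)) {
    stop("apoptosis + S-phase fraction exceeds 1 for some condition")
  }
  check_map <- function(map, cols, what) {
    if (is.null(map)) {
      return(stats::setNames(
        as.data.frame(lapply(cols, function(.) character(0) )), cols))
    }
    stopifnot(all(cols %in% names(map)))
    bad <- setdiff(unique(map$condition), conditions)
    if (length(bad)) {
      stop(what, " references unknown condition(s): ",
           paste(bad, collapse = ", "))
    }
    map
  }
  shift_map <- check_map(shift_map, c("condition", "marker", "delta"),
                         "shift_map")
  dependency_map <- check_map(
    dependency_map, c("condition", "x_ptm", "y_ptm", "strength"),
    "dependency_map")
  if (nrow(dependency_map) &&
      any(dependency_map$strength < 0 | dependency_map$strength > 1)) {
    stop("dependency strengths must be in [0, 1]")
  }
  if (is.null(condition_batches)) {
    condition_batches <- stats::setNames(rep("b1", length(conditions)),
                                         conditions)
  }
  structure(list(
    conditions = conditions, cells_per_condition = as.integer(cells_per_condition),
    marker_panel = marker_panel, shift_map = shift_map,
    dependency_map = dependency_map,
    apoptosis_fraction = apoptosis_fraction,
    s_phase_fraction = s_phase_fraction, g0_share = g0_share,
    doublet_rate = doublet_rate, barcode_scheme = barcode_scheme,
    batch_effects = batch_effects, condition_batches = condition_batches,
    population_mix = population_mix, cofactor = cofactor,
    seed = as.integer(seed)
  ), class = "cytometry_sim_config")
}

# Base arcsinh-scale location/scale per channel. Non-barcode analysis
# channels sit well above 0 so arcsinh-scale translations invert cleanly
# to the raw scale.
.base_channel_params <- function(panel) {
  mus <- numeric(length(panel)); names(mus) <- names(panel)
  sds <- rep(0.5, length(panel)); names(sds) <- names(panel)
  set_mu <- function(role, value) mus[panel == role] <<- value
  set_mu("PTM", 3.5); set_mu("immunophenotype", 3.5)
  set_mu("state", 1.0); set_mu("lineage", 0.8)
  set_mu("DNA", 5.0); set_mu("viability", 0.8); set_mu("barcode", 0.8)
  set_mu("other", 3.0)
  sds[panel %in% c("DNA", "viability", "barcode")] <- 0.3
  sds[panel == "state"] <- 0.35
  # spread PTM/immunophenotype means a little so channels are not clones
  idx <- which(panel %in% c("PTM", "immunophenotype"))
  mus[idx] <- mus[idx] + seq(-0.5, 0.5, length.out = length(idx))
  list(mu = mus, sd = sds)
}

.HI <- 4.5  # arcsinh-scale "positive" level for planted high states
.LO <- 0.8

#' Generate a pooled synthetic cytometry experiment
#'
#' Draws, per condition, `cells_per_condition` singlet cells on the
#' arcsinh scale: base channel distributions are Gaussian there, planted
#' condition effects are exact location shifts, planted PTM dependencies
#' follow `y = s * sigmoid(x) + (1 - s) * noise` with noise sharing y's
#' marginal, cell states (apoptotic / S / G0 / other) set the cPARP, IdU
#' and pRB channels, lineage channels encode the population, and each
#' singlet's barcode channels realise exactly one k-of-n code (high on the
#' k hot channels, low elsewhere). Batch offsets are added on the arcsinh
#' scale, values are inverted to the non-negative raw scale, and doublet
#' events are appended as channel-wise sums of two random singlets
#' (ion-count physics of coincident events).
#'
#' @param config a [cytometry_sim_config()].
#' @return list with elements `table` (a raw-scale [cell_table()] of the
#'   pooled experiment) and `truth` (list: per-cell data.frame with
#'   `condition`, `state`, `population`, `true_code`, `is_doublet`, plus
#'   the planted maps and scheme).
#' @export
generate_cytometry_experiment <- function(config) {
  stopifnot(inherits(config, "cytometry_sim_config"))
  old_seed <- .save_seed(); on.exit(.restore_seed(old_seed))
  set.seed(config$seed)

  panel <- config$marker_panel
  pars <- .base_channel_params(panel)
  bc_channels <- names(panel)[panel == "barcode"]
  scheme <- config$barcode_scheme
  conds <- config$conditions
  n_per <- config$cells_per_condition

  blocks <- vector("list", length(conds))
  truth_blocks <- vector("list", length(conds))
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    n <- n_per
    Z <- matrix(stats::rnorm(n * length(panel)), n, length(panel))
    Z <- sweep(Z, 2, pars$sd, "*")
    Z <- sweep(Z, 2, pars$mu, "+")
    colnames(Z) <- names(panel)

    # cell states
    a <- config$apoptosis_fraction[[cond]]
    s <- config$s_phase_fraction[[cond]]
    rest <- 1 - a - s
    probs <- c(apoptotic = a, S = s, G0 = config$g0_share * rest,
               other = (1 - config$g0_share) * rest)
    state <- sample(names(probs), n, replace = TRUE, prob = probs)
    if ("cPARP" %in% colnames(Z)) {
      Z[, "cPARP"] <- stats::rnorm(n, ifelse(state == "apoptotic", .HI, .LO),
                                   0.35)
    }
    if ("IdU" %in% colnames(Z)) {
      Z[, "IdU"] <- stats::rnorm(n, ifelse(state == "S", .HI, .LO), 0.35)
    }
    if ("pRB" %in% colnames(Z)) {
      Z[, "pRB"] <- stats::rnorm(n, ifelse(state == "G0", .LO, 3.5), 0.35)
    }
    vch <- names(panel)[panel == "viability"][1]
    Z[, vch] <- stats::rnorm(n, ifelse(state == "apoptotic", .HI, .LO), 0.3)

    # population / lineage channels
    mix <- config$population_mix[[cond]]
    if (is.null(mix)) mix <- c(gd_t = 1)
    population <- sample(names(mix), n, replace = TRUE, prob = mix)
    lin_hi <- list(
      epithelial = c("PanCK", "EpCAM"),
      gd_t = c("CD45", "CD3", "gdTCR")
    )
    for (pop in names(lin_hi)) {
      for (ch in intersect(lin_hi[[pop]], colnames(Z))) {
        idx <- population == pop
        Z[idx, ch] <- stats::rnorm(sum(idx), .HI, 0.35)
      }
    }

    # planted location shifts
    sm <- config$shift_map
    if (nrow(sm)) {
      rows <- which(sm$condition == cond)
      for (r in rows) Z[, sm$marker[r]] <- Z[, sm$marker[r]] + sm$delta[r]
    }

    # planted PTM->PTM dependencies: y = s * f(x) + (1-s) * noise, where
    # noise is f at permuted x (same marginal), plus small jitter
    dm <- config$dependency_map
    if (nrow(dm)) {
      rows <- which(dm$condition == cond)
      for (r in rows) {
        xch <- dm$x_ptm[r]; ych <- dm$y_ptm[r]; str <- dm$strength[r]
        x <- Z[, xch]
        mx <- pars$mu[[xch]]; sx <- pars$sd[[xch]]
        my <- pars$mu[[ych]]; sy <- pars$sd[[ych]]
        f <- my - 2 * sy + 4 * sy * stats::plogis(2 * (x - mx) / sx)
        noise <- f[sample.int(n)]
        Z[, ych] <- str * f + (1 - str) * noise + stats::rnorm(n, 0, 0.1)
      }
    }

    # barcode channels: condition ci carries code ci of the scheme.
    # Barcode reagents are high-SNR; hot/cold levels are far separated so
    # singlet codes are unambiguous even in large pools.
    code_idx <- if (length(scheme$code_conditions)) {
      match(names(scheme$code_conditions)[match(cond, scheme$code_conditions)],
            scheme$code_ids)
    } else ci
    code <- scheme$codes[[code_idx]]
    hot <- bc_channels[code]
    Z[, bc_channels] <- stats::rnorm(n * length(bc_channels), 0.5, 0.2)
    Z[, hot] <- stats::rnorm(n * length(hot), 5.0, 0.2)

    # batch offset on the arcsinh scale
    batch <- config$condition_batches[[cond]]
    off <- config$batch_effects[[batch]]
    if (!is.null(off)) {
      if (is.null(names(off))) {
        Z <- Z + off
      } else {
        Z[, names(off)] <- sweep(Z[, names(off), drop = FALSE], 2, off, "+")
      }
    }

    blocks[[ci]] <- Z
    truth_blocks[[ci]] <- data.frame(
      condition = cond, batch = batch, state = state,
      population = population,
      true_code = scheme$code_ids[code_idx], is_doublet = FALSE,
      stringsAsFactors = FALSE
    )
  }

  Z <- do.call(rbind, blocks)
  truth_cells <- do.call(rbind, truth_blocks)
  raw <- config$cofactor * sinh(pmax(Z, 0))

  # doublets: channel-wise sums of two random singlets
  n_total <- nrow(raw)
  n_doub <- round(config$doublet_rate * n_total)
  if (n_doub > 0) {
    i1 <- sample.int(n_total, n_doub, replace = TRUE)
    i2 <- sample.int(n_total, n_doub, replace = TRUE)
    raw <- rbind(raw, raw[i1, , drop = FALSE] + raw[i2, , drop = FALSE])
    truth_cells <- rbind(truth_cells, data.frame(
      condition = "doublet", batch = truth_cells$batch[i1],
      state = NA_character_, population = NA_character_,
      true_code = NA_character_, is_doublet = TRUE,
      stringsAsFactors = FALSE
    ))
  }

  table <- cell_table(raw, panel,
                      condition = "pooled",
                      batch = truth_cells$batch,
                      transform = "raw")
  truth <- list(
    cells = truth_cells,
    shift_map = config$shift_map,
    dependency_map = config$dependency_map,
    apoptosis_fraction = config$apoptosis_fraction,
    s_phase_fraction = config$s_phase_fraction,
    scheme = scheme,
    cofactor = config$cofactor,
    seed = config$seed
  )
  list(table = table, truth = truth)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}
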