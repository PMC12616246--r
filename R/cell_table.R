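#' Single-cell event table
#'
#' A `cell_table` holds one mass-cytometry acquisition (or a slice of one):
#' a cells x channels value matrix, a role for every channel, per-cell
#' labels, and the transform state of the values. Raw ion counts are
#' non-negative; after [arcsinh_transform()] values live on the arcsinh
#' scale and after [batch_mean_center()] on the batch-centred arcsinh
#' scale. The transform state is tracked so a transform is never applied
#' twice.
#'
#' @param values numeric matrix, cells in rows, channels in columns;
#'   column names are the channel names.
#' @param channel_roles named character vector mapping every channel to a
#'   role in `c("PTM", "state", "immunophenotype", "lineage", "DNA",
#'   "viability", "barcode", "other")`.
#' @param condition,batch,replicate per-cell labels, recycled if length 1.
#' @param transform one of `"raw"`, `"arcsinh"`, `"centered"`.
#' @return an object of class `cell_table` with elements `values`,
#'   `channel_roles`, `cells` (a data.frame of per-cell labels including
#'   `assigned_population` and `assigned_barcode`) and `transform`.
#' @export
cell_table <- function(values, channel_roles,
                       condition = "unspecified", batch = "b1",
                       replicate = 1L, transform = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) {
    stop("`values` must have channel names as column names")
  }
  if (anyDuplicated(colnames(values))) {
    stop("channel names must be unique")
  }
  roles <- .valid_roles()
  missing_role <- setdiff(colnames(values), names(channel_roles))
  channel_roles <- c(channel_roles,
                     stats::setNames(rep("other", length(missing_role)),
                                     missing_role))
  channel_roles <- channel_roles[colnames(values)]
  bad <- setdiff(unique(channel_roles), roles)
  if (length(bad)) {
    stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  }
  transform <- match.arg(transform, c("raw", "arcsinh", "centered"))
  if (transform == "raw" && nrow(values) && min(values) < 0) {
    stop("raw-scale values must be non-negative")
  }
  n <- nrow(values)
  cells <- data.frame(
    condition = rep_len(as.character(condition), n),
    batch = rep_len(as.character(batch), n),
    replicate = rep_len(as.integer(replicate), n),
    assigned_population = rep_len("unassigned", n),
    assigned_barcode = rep_len(NA_character_, n),
    stringsAsFactors = FALSE
  )
  structure(
    list(values = values, channel_roles = channel_roles,
         cells = cells, transform = transform),
    class = "cell_table"
  )
}

.valid_roles <- function() {
  c("PTM", "state", "immunophenotype", "lineage", "DNA", "viability",
    "barcode", "other")
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("cell_table: %d cells x %d channels [%s scale]\n",
              nrow(x$values), ncol(x$values), x$transform))
  tab <- table(x$channel_roles)
  cat("channels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat("conditions:", length(unique(x$cells$condition)),
      " batches:", length(unique(x$cells$batch)), "\n")
  invisible(x)
}

#' @export
dim.cell_table <- function(x) dim(x$values)

#' Number of cells in a table
#' @param x a `cell_table`.
#' @return integer cell count.
#' @export
n_cells <- function(x) nrow(x$values)

#' Subset a cell_table by cell index
#'
#' @param x a `cell_table`.
#' @param i integer or logical cell index.
#' @return a `cell_table` with the selected cells, order preserved.
#' @export
subset_cells <- function(x, i) {
  x$values <- x$values[i, , drop = FALSE]
  x$cells <- x$cells[i, , drop = FALSE]
  rownames(x$cells) <- NULL
  x
}

#' Channels with a given role
#' @param x a `cell_table`.
#' @param role one or more roles, e.g. `"PTM"` or `"barcode"`.
#' @return character vector of channel names, in panel order.
#' @export
channels_by_role <- function(x, role) {
  names(x$channel_roles)[x$channel_roles %in% role]
}

#' Bind cell tables row-wise
#'
#' Tables must share channel names, roles and transform state.
#' @param ... `cell_table` objects.
#' @return the combined `cell_table`.
#' @export
bind_cell_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) &&
      !inherits(tabs[[1]], "cell_table")) {
    tabs <- tabs[[1]]
  }
  ref <- tabs[[1]]
  for (t in tabs[-1]) {
    stopifnot(identical(colnames(t$values), colnames(ref$values)),
              identical(t$channel_roles, ref$channel_roles),
              identical(t$transform, ref$transform))
  }
  ref$values <- do.call(rbind, lapply(tabs, `[[`, "values"))
  ref$cells <- do.call(rbind, lapply(tabs, `[[`, "cells"))
  rownames(ref$cells) <- NULL
  ref
}

#' Convert a cell_table to a data.frame
#'
#' Metadata columns (`condition`, `batch`, `replicate`,
#' `assigned_population`, `assigned_barcode`) precede one column per
#' channel.
#' @param x a `cell_table`.
#' @param ... unused.
#' @return a data.frame with one row per cell.
#' @export
as.data.frame.cell_table <- function(x, ...) {
  cbind(x$cells, as.data.frame(x$values))
}

#' Write a cell_table to CSV with a YAML channel manifest
#'
#' The CSV carries one row per cell: metadata columns then channel
#' columns. The manifest records channel roles and the transform state so
#' the table round-trips.
#'
#' @param x a `cell_table`.
#' @param path CSV output path.
#' @param manifest_path YAML manifest path; default `<path>.manifest.yaml`.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(x, path,
                             manifest_path = paste0(path, ".manifest.yaml")) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  manifest <- list(channels = as.list(x$channel_roles),
                   transform = x$transform)
  yaml::write_yaml(manifest, manifest_path)
  invisible(path)
}

#' Read a cell_table from CSV
#'
#' @param path CSV file written by [write_cell_table()] or of the same
#'   shape (metadata columns optional).
#' @param manifest either a YAML manifest path or a named list with a
#'   `channels` map of channel name to role (and optionally `transform`).
#' @return a `cell_table`; channels absent from the manifest keep role
#'   `"other"`.
#' @export
read_cell_table <- function(path, manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) {
      stop("manifest file not found: ", manifest)
    }
    manifest <- yaml::read_yaml(manifest)
  }
  if (is.null(manifest$channels)) {
    stop("manifest error: manifest must contain a `channels` role map")
  }
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("format error reading ", path, ": ",
                             conditionMessage(e))
  )
  meta_cols <- intersect(
    c("condition", "batch", "replicate", "assigned_population",
      "assigned_barcode"), names(df))
  chan_cols <- setdiff(names(df), meta_cols)
  if (!length(chan_cols)) stop("format error: no channel columns in ", path)
  vals <- as.matrix(df[, chan_cols, drop = FALSE])
  roles <- unlist(manifest$channels)
  tab <- cell_table(
    vals, roles,
    condition = if ("condition" %in% meta_cols) df$condition else "unspecified",
    batch = if ("batch" %in% meta_cols) df$batch else "b1",
    replicate = if ("replicate" %in% meta_cols) df$replicate else 1L,
    transform = if (!is.null(manifest$transform)) manifest$transform else "raw"
  )
  if ("assigned_population" %in% meta_cols) {
    tab$cells$assigned_population <- df$assigned_population
  }
  if ("assigned_barcode" %in% meta_cols) {
    tab$cells$assigned_barcode <- df$assigned_barcode
  }
  tab
}

#' Arcsinh-transform a raw-scale table
#'
#' Applies `x -> asinh(x / cofactor)` channel-wise, the standard variance
#' stabilisation for mass-cytometry ion counts. The conventional cofactor
#' for mass cytometry is 5.
#'
#' @param table a raw-scale `cell_table`.
#' @param cofactor positive scalar, or a named vector giving a per-channel
#'   cofactor (unnamed channels fall back to 5).
#' @return the transformed `cell_table` (state `"arcsinh"`).
#' @export
arcsinh_transform <- function(table, cofactor = 5) {
  stopifnot(inherits(table, "cell_table"))
  if (table$transform != "raw") {
    stop("state error: table is already transformed (",
         table$transform, ")")
  }
  if (any(cofactor <= 0)) stop("cofactor must be positive")
  cf <- rep(5, ncol(table$values))
  names(cf) <- colnames(table$values)
  if (is.null(names(cofactor))) {
    cf[] <- cofactor
  } else {
    cf[names(cofactor)] <- cofactor
  }
  table$values <- asinh(sweep(table$values, 2, cf, "/"))
  table$transform <- "arcsinh"
  table
}

#' Mean-centre channels within acquisition batches
#'
#' Subtracts, within each batch, each channel's batch mean, removing
#' additive batch effects on the arcsinh scale. Batches with no cells are
#' skipped with a warning.
#'
#' @param table an arcsinh-scale `cell_table` with per-cell batch labels.
#' @param batch_label optional character vector overriding
#'   `table$cells$batch`.
#' @return the centred `cell_table` (state `"centered"`); per-batch
#'   per-channel means of the output are 0 to 1e-9.
#' @export
batch_mean_center <- function(table, batch_label = NULL) {
  stopifnot(inherits(table, "cell_table"))
  if (table$transform == "raw") {
    stop("state error: arcsinh-transform before batch centering")
  }
  if (table$transform == "centered") {
    stop("state error: table is already batch-centered")
  }
  batches <- if (is.null(batch_label)) table$cells$batch else
    rep_len(as.character(batch_label), nrow(table$values))
  for (b in unique(batches)) {
    idx <- which(batches == b)
    if (!length(idx)) {
      warning("batch with 0 cells skipped: ", b)
      next
    }
    mu <- colMeans(table$values[idx, , drop = FALSE])
    table$values[idx, ] <- sweep(table$values[idx, , drop = FALSE], 2, mu)
  }
  table$transform <- "centered"
  table
}

#' Gate specification
#'
#' A gate names a population and lists channels that must exceed
#' (`positive`) or not exceed (`negative`) fixed thresholds. Thresholds
#' are explicit values on the table's current scale; they are not fitted.
#'
#' @param population population name, e.g. `"epithelial"` or `"gd_t"`.
#' @param positive named numeric vector: channel -> threshold; a cell must
#'   have value > threshold on each.
#' @param negative named numeric vector: channel -> threshold; a cell must
#'   have value <= threshold on each.
#' @return a `gate_spec` object.
#' @export
gate_spec <- function(population, positive = numeric(), negative = numeric()) {
  positive <- unlist(positive); negative <- unlist(negative)
  if (length(positive) && (is.null(names(positive)) ||
                           !all(nzchar(names(positive))))) {
    stop("positive thresholds must be named by channel")
  }
  if (length(negative) && (is.null(names(negative)) ||
                           !all(nzchar(names(negative))))) {
    stop("negative thresholds must be named by channel")
  }
  if (!all(is.finite(c(positive, negative)))) {
    stop("gate thresholds must be finite")
  }
  if (length(intersect(names(positive), names(negative)))) {
    stop("a channel cannot be both positive and negative in one gate")
  }
  structure(list(population = population,
                 positive = positive, negative = negative),
            class = "gate_spec")
}

#' Assign a population label by threshold gating
#'
#' Cells meeting every positive requirement (value strictly above the
#' threshold) and every negative requirement (value at or below the
#' threshold) receive the gate's population label; other cells keep their
#' current label. Cell order is preserved and gating is idempotent.
#'
#' @param table a `cell_table`.
#' @param gate a [gate_spec()].
#' @return the `cell_table` with `assigned_population` updated.
#' @export
gate_population <- function(table, gate) {
  stopifnot(inherits(table, "cell_table"), inherits(gate, "gate_spec"))
  chans <- c(names(gate$positive), names(gate$negative))
  miss <- setdiff(chans, colnames(table$values))
  if (length(miss)) {
    stop("gate channel(s) not in table: ", paste(miss, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(table$values))
  for (ch in names(gate$positive)) {
    keep <- keep & table$values[, ch] > gate$positive[[ch]]
  }
  for (ch in names(gate$negative)) {
    keep <- keep & table$values[, ch] <= gate$negative[[ch]]
  }
  table$cells$assigned_population[keep] <- gate$population
  table
}

#' Extract the cells of one gated population
#' @param table a gated `cell_table`.
#' @param population population label to keep.
#' @return a `cell_table` restricted to that population.
#' @export
gated_population <- function(table, population) {
  subset_cells(table, table$cells$assigned_population == population)
}
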