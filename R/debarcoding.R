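#' Enumerate a combinatorial k-of-n barcode scheme
#'
#' A k-of-n scheme labels each pooled sample with high intensity on
#' exactly `k_hot` of `n_channels` barcode isotopes; the 9-choose-4 layout
#' gives 126 codes. Codes are enumerated in lexicographic order of channel
#' indices.
#'
#' @param n_channels number of barcode channels.
#' @param k_hot number of hot channels per code (0 < k_hot < n_channels).
#' @param conditions optional character vector mapped onto codes spaced
#'   evenly across the enumeration, so that even a partial plate keeps
#'   every barcode channel represented in both hot and cold states (a
#'   requirement of the per-channel percentile rescaling in
#'   [debarcode()]).
#' @return a `barcode_scheme`: list with `n_channels`, `k_hot`, `codes`
#'   (list of integer k-subsets), `code_ids` (e.g. `"1.3.5.7"`) and
#'   `code_conditions` (named map code id -> condition, possibly empty).
#' @export
enumerate_scheme <- function(n_channels, k_hot, conditions = NULL) {
  if (k_hot <= 0 || k_hot >= n_channels) {
    stop("configuration error: need 0 < k_hot < n_channels")
  }
  combs <- utils::combn(n_channels, k_hot)
  codes <- lapply(seq_len(ncol(combs)), function(j) combs[, j])
  code_ids <- vapply(codes, paste, character(1), collapse = ".")
  code_conditions <- character(0)
  if (!is.null(conditions)) {
    if (length(conditions) > length(codes)) {
      stop("more conditions than codes in the scheme")
    }
    picked <- ceiling(seq_along(conditions) *
                        length(codes) / length(conditions))
    code_conditions <- stats::setNames(as.character(conditions),
                                       code_ids[picked])
  }
  structure(list(n_channels = n_channels, k_hot = k_hot,
                 codes = codes, code_ids = code_ids,
                 code_conditions = code_conditions),
            class = "barcode_scheme")
}

#' @export
print.barcode_scheme <- function(x, ...) {
  cat(sprintf("barcode_scheme: %d-choose-%d, %d codes, %d mapped to conditions\n",
              x$n_channels, x$k_hot, length(x$codes),
              length(x$code_conditions)))
  invisible(x)
}

# robust per-channel rescale to [0,1] over a percentile window
.rescale_barcodes <- function(B, lower = 0.01, upper = 0.99) {
  apply(B, 2, function(v) {
    q <- stats::quantile(v, c(lower, upper), names = FALSE, type = 7)
    if (q[2] <= q[1]) return(rep(0, length(v)))
    pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1)
  })
}

#' Assign cells to combinatorial barcode codes
#'
#' Single-pass rank debarcoding: each barcode channel is rescaled to
#' \[0,1\] across cells over its 1st-99th percentile window; per cell the
#' channels are ranked, the candidate code is the set of the top `k_hot`
#' channels, and the separation is the gap between the k-th and (k+1)-th
#' ranked rescaled intensity. A cell is assigned iff its top-k set is a
#' valid scheme code and its separation reaches the threshold; doublets
#' (more than k bright channels) fail on separation. Ties at the k/(k+1)
#' boundary give separation 0 and are left unassigned.
#'
#' @param table an arcsinh-scale (or centered) [cell_table()] containing
#'   the scheme's barcode channels.
#' @param scheme a [enumerate_scheme()] result.
#' @param separation_threshold minimum separation in \[0,1\] for
#'   assignment; default 0.3.
#' @return data.frame with one row per cell: `cell`, `code` (code id or
#'   NA), `separation`, `assigned`.
#' @export
debarcode <- function(table, scheme, separation_threshold = 0.3) {
  stopifnot(inherits(table, "cell_table"),
            inherits(scheme, "barcode_scheme"))
  if (table$transform == "raw") {
    stop("state error: arcsinh-transform the table before debarcoding")
  }
  bc <- channels_by_role(table, "barcode")
  if (length(bc) != scheme$n_channels) {
    stop("table has ", length(bc), " barcode channels; scheme expects ",
         scheme$n_channels)
  }
  B <- .rescale_barcodes(table$values[, bc, drop = FALSE])
  k <- scheme$k_hot
  n <- nrow(B)
  valid <- stats::setNames(seq_along(scheme$code_ids), scheme$code_ids)
  code <- character(n); sep <- numeric(n)
  for (i in seq_len(n)) {
    o <- order(B[i, ], decreasing = TRUE)
    sep[i] <- B[i, o[k]] - B[i, o[k + 1]]
    code[i] <- paste(sort(o[seq_len(k)]), collapse = ".")
  }
  ok <- !is.na(match(code, scheme$code_ids)) & sep >= separation_threshold
  data.frame(cell = seq_len(n),
             code = ifelse(ok, code, NA_character_),
             separation = sep, assigned = ok,
             stringsAsFactors = FALSE)
}

#' Split a pooled table into per-condition tables
#'
#' Routes each assigned cell to the condition its code maps to (codes
#' with no condition mapping go to `"unmapped"` with a warning);
#' unassigned cells are counted in the QC summary. The outputs partition
#' the input: assigned + unassigned = total cells.
#'
#' @param table the pooled [cell_table()].
#' @param calls output of [debarcode()].
#' @param scheme the [enumerate_scheme()] used (must carry a
#'   code -> condition map).
#' @return list with `tables` (named list condition -> `cell_table`) and
#'   `qc` (data.frame: code, condition, n_assigned, median_separation;
#'   plus attribute `n_unassigned`).
#' @export
split_by_condition <- function(table, calls, scheme) {
  stopifnot(nrow(calls) == nrow(table$values))
  cond_of <- scheme$code_conditions
  assigned <- which(calls$assigned)
  codes <- calls$code[assigned]
  cond <- unname(cond_of[codes])
  unmapped <- is.na(cond)
  if (any(unmapped)) {
    warning(sum(unmapped), " assigned cells carry codes with no condition",
            " mapping; routed to 'unmapped'")
    cond[unmapped] <- "unmapped"
  }
  tables <- list()
  for (cd in unique(cond)) {
    idx <- assigned[cond == cd]
    tb <- subset_cells(table, idx)
    tb$cells$condition <- cd
    tb$cells$assigned_barcode <- calls$code[idx]
    tables[[cd]] <- tb
  }
  qc <- do.call(rbind, lapply(names(cond_of), function(code) {
    idx <- assigned[codes == code]
    data.frame(code = code, condition = cond_of[[code]],
               n_assigned = length(idx),
               median_separation = if (length(idx))
                 stats::median(calls$separation[idx]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(qc) <- NULL
  attr(qc, "n_unassigned") <- sum(!calls$assigned)
  list(tables = tables, qc = qc)
}
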