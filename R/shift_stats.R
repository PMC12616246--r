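#' Signed earth mover's distance between two marker distributions
#'
#' The magnitude is the exact 1-D Wasserstein-1 distance between the two
#' empirical distributions — the integral of the absolute CDF difference,
#' computed on the pooled support so unequal sample sizes are handled
#' deterministically without subsampling. The sign encodes the direction
#' of the shift: positive when the test median exceeds the reference
#' median, negative when below; a median tie keeps sign +. For equal-size
#' samples the magnitude equals the mean absolute difference of the
#' sorted samples.
#'
#' @param test,reference non-empty numeric samples of one marker, on the
#'   same (transformed) scale.
#' @return signed EMD (real); `signed_emd(x, x) == 0`.
#' @export
signed_emd <- function(test, reference) {
  if (!length(test) || !length(reference)) {
    stop("value error: empty sample in signed_emd")
  }
  if (anyNA(test) || anyNA(reference)) stop("samples must not contain NA")
  xs <- sort(test); ys <- sort(reference)
  pooled <- sort(c(xs, ys))
  dz <- diff(pooled)
  left <- pooled[-length(pooled)]
  Fx <- findInterval(left, xs) / length(xs)
  Fy <- findInterval(left, ys) / length(ys)
  mag <- sum(dz * abs(Fx - Fy))
  sgn <- if (stats::median(test) >= stats::median(reference)) 1 else -1
  sgn * mag
}

#' Per-marker signed EMD of a condition against its reference
#'
#' Computes [signed_emd()] for every included marker of a test condition
#' against a matched control, plus the x-bar EMD summary — the
#' coordinate sliced Wasserstein distance: the mean of the absolute
#' per-marker EMDs, irrespective of direction.
#'
#' By default all non-barcode, non-DNA, non-viability channels are
#' included.
#'
#' @param test,reference [cell_table()] objects on the same transform
#'   state (conventionally arcsinh + batch-centered).
#' @param markers optional character vector overriding marker inclusion.
#' @param condition,reference_id labels stored in the result.
#' @return a `shift_result`: list with `condition`, `reference`,
#'   `markers` (data.frame: marker, signed_emd, abs_emd) and `xbar_emd`.
#' @export
compute_shifts <- function(test, reference, markers = NULL,
                           condition = "test", reference_id = "reference") {
  stopifnot(inherits(test, "cell_table"), inherits(reference, "cell_table"))
  if (!identical(test$transform, reference$transform)) {
    stop("test and reference are on different transform states")
  }
  if (is.null(markers)) {
    markers <- names(test$channel_roles)[
      !test$channel_roles %in% c("barcode", "DNA", "viability")]
  }
  miss <- setdiff(markers, colnames(test$values))
  if (length(miss)) stop("marker(s) missing: ", paste(miss, collapse = ", "))
  se <- vapply(markers, function(m) {
    signed_emd(test$values[, m], reference$values[, m])
  }, numeric(1))
  res <- structure(list(
    condition = condition, reference = reference_id,
    markers = data.frame(marker = markers, signed_emd = unname(se),
                         abs_emd = abs(unname(se)),
                         stringsAsFactors = FALSE),
    xbar_emd = mean(abs(se))
  ), class = "shift_result")
  res
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf("shift_result: %s vs %s, %d markers, xbar EMD = %.4f\n",
              x$condition, x$reference, nrow(x$markers), x$xbar_emd))
  invisible(x)
}

#' Mean absolute EMD over included markers
#'
#' @param shifts a `shift_result` from [compute_shifts()], or a numeric
#'   vector of signed EMDs.
#' @return the x-bar EMD (>= 0).
#' @export
xbar_emd <- function(shifts) {
  v <- if (inherits(shifts, "shift_result")) shifts$markers$signed_emd
       else shifts
  if (!length(v)) stop("value error: no markers to average")
  mean(abs(v))
}

#' Fraction of values strictly above a threshold
#' @param values non-empty numeric sample.
#' @param threshold positivity cutoff (values > threshold count).
#' @return fraction in \[0,1\].
#' @export
fraction_positive <- function(values, threshold) {
  if (!length(values)) stop("value error: empty sample")
  mean(values > threshold)
}

#' Therapeutic apoptosis relative to a monoculture baseline
#'
#' The apoptotic (e.g. cPARP-positive) fraction of the gated target-cell
#' population in co-culture minus the baseline fraction measured in the
#' matched monoculture control, in percentage points. Negative values
#' indicate protection.
#'
#' @param coculture,monoculture_baseline [cell_table()] objects gated to
#'   the target (epithelial) population.
#' @param apoptosis_channel channel name, default `"cPARP"`.
#' @param threshold positivity threshold on the tables' scale.
#' @return difference in percentage points.
#' @export
therapeutic_apoptosis <- function(coculture, monoculture_baseline,
                                  apoptosis_channel = "cPARP",
                                  threshold = 0) {
  for (nm in c("coculture", "baseline")) {
    tb <- if (nm == "coculture") coculture else monoculture_baseline
    if (!nrow(tb$values)) {
      stop("value error: empty gated population in ", nm)
    }
  }
  100 * (fraction_positive(coculture$values[, apoptosis_channel], threshold) -
         fraction_positive(monoculture_baseline$values[, apoptosis_channel],
                           threshold))
}

#' Classify cell states from apoptosis, S-phase and proliferation markers
#'
#' Priority hierarchy: apoptotic if cPARP-positive; else S if
#' IdU-positive; else G0 if pRB-negative; else other. Exactly one state
#' per cell.
#'
#' @param table a [cell_table()] with the three channels.
#' @param thresholds named numeric vector with entries `cPARP`, `IdU`,
#'   `pRB` (positivity cutoffs on the table's scale; channel names may be
#'   remapped via `channels`).
#' @param channels named character vector mapping roles `cPARP`, `IdU`,
#'   `pRB` to channel names.
#' @return character vector of states in
#'   `c("apoptotic", "S", "G0", "other")`, one per cell.
#' @export
classify_cell_state <- function(table,
                                thresholds = c(cPARP = 0, IdU = 0, pRB = 0),
                                channels = c(cPARP = "cPARP", IdU = "IdU",
                                             pRB = "pRB")) {
  miss <- setdiff(unname(channels), colnames(table$values))
  if (length(miss)) {
    stop("configuration error: missing channel(s): ",
         paste(miss, collapse = ", "))
  }
  cparp <- table$values[, channels[["cPARP"]]] > thresholds[["cPARP"]]
  idu <- table$values[, channels[["IdU"]]] > thresholds[["IdU"]]
  prb <- table$values[, channels[["pRB"]]] > thresholds[["pRB"]]
  ifelse(cparp, "apoptotic", ifelse(idu, "S", ifelse(!prb, "G0", "other")))
}

#' Counts of cell states in a gated population
#' @inheritParams classify_cell_state
#' @return named integer vector over apoptotic, S, G0, other, summing to
#'   the population size.
#' @export
cell_state_counts <- function(table,
                              thresholds = c(cPARP = 0, IdU = 0, pRB = 0),
                              channels = c(cPARP = "cPARP", IdU = "IdU",
                                           pRB = "pRB")) {
  st <- classify_cell_state(table, thresholds, channels)
  out <- c(apoptotic = 0L, S = 0L, G0 = 0L, other = 0L)
  tab <- table(factor(st, levels = names(out)))
  out[names(tab)] <- as.integer(tab)
  out
}

#' Percentage change in marker positivity relative to a control
#'
#' `100 * (fraction_test - fraction_control) / fraction_control`. When
#' the control fraction is 0 the change is undefined and `NA` is returned
#' with a warning.
#'
#' @param test,control [cell_table()] objects.
#' @param channel marker channel name.
#' @param threshold positivity threshold.
#' @return percentage change (real), or `NA` if undefined.
#' @export
percent_change_positive <- function(test, control, channel, threshold = 0) {
  ft <- fraction_positive(test$values[, channel], threshold)
  fc <- fraction_positive(control$values[, channel], threshold)
  if (fc == 0) {
    warning("control fraction is 0 for ", channel, "; change undefined")
    return(NA_real_)
  }
  100 * (ft - fc) / fc
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-adjusted Kendall correlation between two equal-length vectors,
#' as used to relate condition-level x-bar EMD to cytotoxicity.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return tau in \[-1, 1\].
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("value error: length mismatch")
  if (length(x) < 2) stop("value error: need at least 2 observations")
  stats::cor(x, y, method = "kendall")
}
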