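#' Enumerate ordered PTM marker pairs
#'
#' All ordered pairs (x, y), x != y, in panel order — for a panel of p
#' markers this is p(p-1) pairs (110 for the 11-PTM panel).
#'
#' @param panel character vector of unique PTM marker names (length >= 2).
#' @return data.frame with columns `x_ptm`, `y_ptm` in deterministic
#'   panel-order sequence.
#' @export
enumerate_pairs <- function(panel) {
  if (length(panel) < 2) stop("panel must contain at least 2 markers")
  if (anyDuplicated(panel)) stop("panel names must be unique")
  grid <- expand.grid(y_ptm = panel, x_ptm = panel,
                      stringsAsFactors = FALSE)[, c("x_ptm", "y_ptm")]
  grid <- grid[grid$x_ptm != grid$y_ptm, ]
  # panel-order: outer loop over x, inner over y
  grid <- grid[order(match(grid$x_ptm, panel), match(grid$y_ptm, panel)), ]
  rownames(grid) <- NULL
  grid
}

# clip to a central percentile window, then min/max rescale to [0, 1]
.rescale_unit <- function(v, lower = 0.001, upper = 0.999) {
  q <- stats::quantile(v, c(lower, upper), names = FALSE, type = 7)
  v <- pmin(pmax(v, q[1]), q[2])
  rng <- range(v)
  if (rng[2] <= rng[1]) return(rep(0, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

# distance from each grid point (rows of G, 2 cols) to its k-th nearest
# data point (rows of X); exact. Uses a kd-tree when RANN is available,
# otherwise a chunked brute-force search — identical results either way.
.knn_radius <- function(G, X, k) {
  if (requireNamespace("RANN", quietly = TRUE)) {
    return(RANN::nn2(X, G, k = k, treetype = "kd",
                     searchtype = "standard")$nn.dists[, k])
  }
  n <- nrow(X)
  x2 <- rowSums(X^2)
  out <- numeric(nrow(G))
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1L, nrow(G), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(G))
    D2 <- outer(rowSums(G[idx, , drop = FALSE]^2), x2, "+") -
      2 * G[idx, , drop = FALSE] %*% t(X)
    D2[D2 < 0] <- 0
    out[idx] <- sqrt(apply(D2, 1, function(r) sort.int(r, partial = k)[k]))
  }
  out
}

#' kNN density-resampled estimate of mutual information (kNN-DREMI)
#'
#' Scores the strength of the response function y = f(x) between two
#' markers, insensitive to the population density along x. Pipeline:
#' (1) rescale x and y to \[0,1\] (min/max after clipping the
#' 0.1/99.9 percentile tails); (2) evaluate a joint density estimate on a
#' fine (n_bins * n_mesh)^2 grid with the k-nearest-neighbour estimator
#' density ~ k / (N * pi * r_k^2), r_k the distance to the k-th nearest
#' data point; (3) aggregate mesh cells into n_bins x n_bins coarse bins;
#' (4) renormalise each x-column into a conditional distribution
#' p(y | x_i), dropping empty columns; (5) return the mutual information,
#' in bits, of the density-resampled joint q(x, y) = p(y | x_i) / n_cols
#' against its marginals. Deterministic for fixed inputs and settings;
#' bounded by log2(n_bins).
#'
#' @param x,y equal-length paired marker samples (length >= k + 1).
#' @param k neighbours for the density estimate (default 10).
#' @param n_bins coarse bins per axis (default 20).
#' @param n_mesh fine mesh cells per coarse bin per axis (default 3).
#' @return DREMI score in bits (0 if x or y has zero variance).
#' @export
knn_dremi <- function(x, y, k = 10, n_bins = 20, n_mesh = 3) {
  if (length(x) != length(y)) stop("value error: x and y lengths differ")
  if (length(x) < k + 1) {
    stop("value error: need at least k + 1 = ", k + 1, " cells")
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("value error: non-finite values")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  xs <- .rescale_unit(x)
  ys <- .rescale_unit(y)
  if (all(xs == 0) || all(ys == 0)) return(0)
  G <- n_bins * n_mesh
  centers <- (seq_len(G) - 0.5) / G
  grid <- cbind(rep(centers, times = G), rep(centers, each = G))  # (x, y)
  rk <- .knn_radius(grid, cbind(xs, ys), k)
  rk[rk < 1e-12] <- 1e-12
  dens <- k / (length(xs) * pi * rk^2)
  fine <- matrix(dens, nrow = G)  # rows = x index, cols = y index
  # aggregate n_mesh x n_mesh blocks into coarse bins
  fac <- rep(seq_len(n_bins), each = n_mesh)
  coarse <- rowsum(fine, fac)              # collapse x
  coarse <- t(rowsum(t(coarse), fac))      # collapse y; rows x, cols y
  colsums <- rowSums(coarse)               # per-x-bin mass
  keep <- colsums > 0
  if (!any(keep)) return(0)
  cond <- coarse[keep, , drop = FALSE] / colsums[keep]   # p(y | x_i)
  q <- cond / nrow(cond)                   # resampled joint
  qx <- rowSums(q)
  qy <- colSums(q)
  nz <- q > 0
  mi <- sum(q[nz] * log2(q[nz] / (outer(qx, qy)[nz])))
  max(mi, 0)
}

#' DREMI scores for every ordered PTM pair of a condition
#'
#' @param table a gated single-population [cell_table()].
#' @param panel character vector of PTM channel names (>= 2).
#' @param k,n_bins,n_mesh estimator settings, see [knn_dremi()].
#' @return a `dremi_table`: list with `condition`, `scores` (data.frame:
#'   x_ptm, y_ptm, dremi — p(p-1) rows), and `settings`.
#' @export
dremi_table <- function(table, panel = default_ptm_panel(),
                        k = 10, n_bins = 20, n_mesh = 3) {
  stopifnot(inherits(table, "cell_table"))
  miss <- setdiff(panel, colnames(table$values))
  if (length(miss)) {
    stop("configuration error: panel channel(s) missing: ",
         paste(miss, collapse = ", "))
  }
  pairs <- enumerate_pairs(panel)
  pairs$dremi <- vapply(seq_len(nrow(pairs)), function(i) {
    knn_dremi(table$values[, pairs$x_ptm[i]],
              table$values[, pairs$y_ptm[i]],
              k = k, n_bins = n_bins, n_mesh = n_mesh)
  }, numeric(1))
  structure(list(condition = unique(table$cells$condition)[1],
                 scores = pairs,
                 settings = list(k = k, n_bins = n_bins, n_mesh = n_mesh)),
            class = "dremi_table")
}

#' @export
print.dremi_table <- function(x, ...) {
  cat(sprintf("dremi_table: condition %s, %d pairs (k=%d, bins=%d, mesh=%d)\n",
              x$condition, nrow(x$scores), x$settings$k,
              x$settings$n_bins, x$settings$n_mesh))
  invisible(x)
}

#' Delta-DREMI rewiring vector of a condition against its control
#'
#' Per ordered PTM pair, `DREMI(condition) - DREMI(control)`; the vector
#' over all pairs quantifies signalling-network rewiring.
#'
#' @param condition,control `dremi_table` objects over identical panels
#'   and settings.
#' @return data.frame with `x_ptm`, `y_ptm`, `delta_dremi`.
#' @export
delta_dremi <- function(condition, control) {
  stopifnot(inherits(condition, "dremi_table"),
            inherits(control, "dremi_table"))
  if (!identical(condition$scores[, c("x_ptm", "y_ptm")],
                 control$scores[, c("x_ptm", "y_ptm")]) ||
      !identical(condition$settings, control$settings)) {
    stop("configuration error: panel or settings mismatch")
  }
  data.frame(condition$scores[, c("x_ptm", "y_ptm")],
             delta_dremi = condition$scores$dremi - control$scores$dremi)
}
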