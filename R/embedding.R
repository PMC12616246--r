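#' Assemble a condition-by-feature matrix
#'
#' Rows are conditions, columns are features (per-marker signed EMDs or
#' per-pair delta-DREMI values). Missing entries are zero-filled with a
#' warning reporting the count.
#'
#' @param long data.frame with columns `condition`, `feature`, `value`.
#' @param feature_kind tag, e.g. `"signed_emd"` or `"delta_dremi"`.
#' @return numeric matrix with condition row names and a `feature_kind`
#'   attribute.
#' @export
condition_matrix <- function(long, feature_kind = "feature") {
  stopifnot(all(c("condition", "feature", "value") %in% names(long)))
  conds <- unique(long$condition)
  feats <- unique(long$feature)
  if (anyDuplicated(paste(long$condition, long$feature, sep = "\r"))) {
    stop("duplicate (condition, feature) entries")
  }
  M <- matrix(NA_real_, length(conds), length(feats),
              dimnames = list(conds, feats))
  M[cbind(match(long$condition, conds), match(long$feature, feats))] <-
    long$value
  n_miss <- sum(is.na(M))
  if (n_miss) {
    warning(n_miss, " missing (condition, feature) entries zero-filled")
    M[is.na(M)] <- 0
  }
  attr(M, "feature_kind") <- feature_kind
  M
}

.fix_pc_signs <- function(scores, rotation) {
  for (j in seq_len(ncol(scores))) {
    l <- rotation[, j]
    if (l[which.max(abs(l))] < 0) scores[, j] <- -scores[, j]
  }
  scores
}

#' PCA embedding of a condition matrix
#'
#' Column-centred principal component analysis; deterministic, with the
#' sign of each component fixed by making its largest-magnitude loading
#' positive.
#'
#' @param matrix conditions x features numeric matrix (>= 2 rows).
#' @param n_components number of components (default 2).
#' @return an `embedding2d`: data.frame with `condition`, `dim1`, `dim2`
#'   (and further dims if requested), with attributes `method` and
#'   `settings`.
#' @export
pca_embed <- function(matrix, n_components = 2) {
  if (nrow(matrix) < n_components) {
    stop("value error: fewer rows than components")
  }
  p <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  scores <- .fix_pc_signs(p$x[, seq_len(k), drop = FALSE],
                          p$rotation[, seq_len(k), drop = FALSE])
  if (k < n_components) {
    scores <- cbind(scores, matrix(0, nrow(scores), n_components - k))
  }
  out <- data.frame(condition = rownames(matrix),
                    stringsAsFactors = FALSE)
  for (j in seq_len(n_components)) out[[paste0("dim", j)]] <- scores[, j]
  attr(out, "method") <- "pca"
  attr(out, "settings") <- list(n_components = n_components)
  class(out) <- c("embedding2d", "data.frame")
  out
}

#' Diffusion-potential embedding of a condition matrix
#'
#' A structure-preserving nonlinear embedding for condition-level feature
#' vectors: pairwise Euclidean distances; adaptive-bandwidth alpha-decay
#' kernel `K_ij = exp(-(d_ij / sigma_i)^alpha)` with `sigma_i` the
#' distance to the k-th nearest row, symmetrised; row-normalised to a
#' Markov transition matrix; powered to `t` diffusion steps; the
#' potential coordinates are `-log` of the transition probabilities
#' (floored at 1e-7); classical metric MDS then maps the potential rows
#' to 2-D. Deterministic for fixed inputs; the seed is recorded in the
#' settings for provenance.
#'
#' @param matrix conditions x features numeric matrix (>= 3 rows).
#' @param k adaptive-bandwidth neighbour (default 5; must be < n rows).
#' @param alpha kernel decay exponent (default 10).
#' @param t diffusion time (default 10).
#' @param seed recorded seed (default 42).
#' @return an `embedding2d` data.frame (`condition`, `dim1`, `dim2`) with
#'   `method = "diffusion_potential"`.
#' @export
diffusion_potential_embed <- function(matrix, k = 5, alpha = 10, t = 10,
                                      seed = 42) {
  if (nrow(matrix) < 3) stop("value error: need at least 3 rows")
  if (k >= nrow(matrix)) stop("value error: k must be < number of rows")
  D <- as.matrix(stats::dist(matrix))
  sigma <- apply(D, 1, function(r) sort(r)[k + 1])  # k-th nearest other row
  sigma[sigma <= 0] <- min(D[D > 0], 1)
  K <- exp(-(sweep(D, 1, sigma, "/"))^alpha)
  K <- (K + t(K)) / 2
  P <- K / rowSums(K)
  Pt <- diag(nrow(P))
  for (i in seq_len(t)) Pt <- Pt %*% P
  potential <- -log(pmax(Pt, 1e-7))
  coords <- stats::cmdscale(stats::dist(potential), k = 2)
  out <- data.frame(condition = rownames(matrix),
                    dim1 = coords[, 1], dim2 = coords[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "diffusion_potential"
  attr(out, "settings") <- list(k = k, alpha = alpha, t = t, seed = seed)
  class(out) <- c("embedding2d", "data.frame")
  out
}
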