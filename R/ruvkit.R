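ruv_lib_sizes <- function(counts, normalization = c("column", "upperquartile")) {
  normalization <- match.arg(normalization)
  lib <- colSums(counts)
  if (normalization == "upperquartile") {
    uq <- apply(counts, 2, function(v) quantile(v[v > 0], 0.75))
    if (any(!is.finite(uq)))
      stop("a sample has no positive counts; cannot upper-quartile normalize")
    lib <- uq / mean(uq) * mean(lib)
  }
  lib
}

#' Residuals of log-CPM on the known design
#'
#' Fits, peak by peak, an ordinary least-squares model of log2-CPM on the
#' condition factor and returns the residual matrix (peaks x samples). With
#' a two-group design the residuals are simply the log-CPM values minus
#' their group means, so they sum to zero within each group and are
#' orthogonal to the design columns. These residuals carry whatever
#' systematic variation the known design does not explain - the raw
#' material for unwanted-variation factor analysis.
#'
#' @param counts non-negative count matrix (peaks x samples).
#' @param condition factor over the columns (any number of levels).
#' @param prior_count pseudo-count for [logcpm_transform()].
#' @param normalization library-size mode: plain column sums
#'   (\code{"column"}) or upper-quartile effective sizes
#'   (\code{"upperquartile"}).
#' @return real residual matrix, peaks x samples.
#' @export
residual_matrix <- function(counts, condition, prior_count = 2,
                            normalization = "column") {
  counts <- as.matrix(counts)
  condition <- factor(condition)
  if (length(condition) != ncol(counts))
    stop("one condition label per sample is required")
  design <- model.matrix(~ condition)
  if (qr(design)$rank < ncol(design)) stop("design matrix is rank deficient")
  lc <- logcpm_transform(counts, ruv_lib_sizes(counts, normalization),
                         prior_count)
  hat <- design %*% chol2inv(chol(crossprod(design))) %*% t(design)
  lc - lc %*% t(hat)
}

#' Remove unwanted variation by residual factor analysis
#'
#' RUVr-style correction: the first \code{k} sample-side singular vectors of
#' the residual matrix (see [residual_matrix()]) define the unwanted factors
#' \code{W} (samples x k, orthonormal, sign fixed so each column's
#' largest-magnitude entry is positive); per-peak regression of log-CPM on
#' \code{W} gives the loadings \code{alpha}; corrected log-CPM is the input
#' minus \code{W alpha}, and corrected counts are obtained by inverting the
#' log-CPM transform with the original library sizes, rounding, and clamping
#' at zero. With \code{k = 0} the input is returned up to round-trip
#' rounding. Supplying a pre-computed \code{W} skips factor estimation and
#' removes exactly those directions (re-applying with the same \code{W} is
#' then a no-op, since the corrected values are orthogonal to it).
#'
#' @inheritParams residual_matrix
#' @param k number of unwanted factors to remove (0 <= k < samples);
#'   default 3.
#' @param W optional samples x k factor matrix to use instead of estimating
#'   one from the residuals.
#' @return an object of class \code{"ruv_fit"}: a list with
#'   \code{corrected_counts} (integer matrix), \code{corrected_logcpm},
#'   \code{W}, \code{alpha} (k x peaks), \code{k}, and the library sizes
#'   used.
#' @export
ruvr_correct <- function(counts, condition, k = 3, prior_count = 2,
                         normalization = "column", W = NULL) {
  counts <- as.matrix(counts)
  k <- as.integer(k)
  if (k < 0L || k >= ncol(counts))
    stop("'k' must satisfy 0 <= k < number of samples")
  lib <- ruv_lib_sizes(counts, normalization)
  lc <- logcpm_transform(counts, lib, prior_count)
  if (is.null(W)) {
    if (k > 0L) {
      res <- residual_matrix(counts, condition, prior_count, normalization)
      sv <- svd(scale(t(res), center = TRUE, scale = FALSE), nu = k, nv = 0)
      W <- sv$u[, seq_len(k), drop = FALSE]
      ## Sign convention: largest-magnitude entry of each column positive.
      for (j in seq_len(k)) {
        top <- which.max(abs(W[, j]))
        if (W[top, j] < 0) W[, j] <- -W[, j]
      }
    } else {
      W <- matrix(0, ncol(counts), 0)
    }
  } else {
    W <- as.matrix(W)
    if (nrow(W) != ncol(counts)) stop("'W' must have one row per sample")
    k <- ncol(W)
  }
  alpha <- if (k > 0L) t(qr.solve(crossprod(W), t(lc %*% W)))  # peaks x k
           else matrix(0, nrow(counts), 0)
  corrected_lc <- lc - if (k > 0L) alpha %*% t(W) else 0
  corrected <- pmax(round(inverse_logcpm(corrected_lc, lib, prior_count)), 0)
  structure(list(corrected_counts = corrected,
                 corrected_logcpm = corrected_lc,
                 W = W, alpha = if (k > 0L) t(alpha) else matrix(0, 0, nrow(counts)),
                 k = k, lib_sizes = lib),
            class = "ruv_fit")
}

#' @export
print.ruv_fit <- function(x, ...) {
  cat(sprintf("RUV residual-factor correction: %d factor(s) removed from %d samples x %d peaks\n",
              x$k, nrow(x$W), ncol(x$alpha)))
  invisible(x)
}

#' Principal-component diagnostic of a count matrix
#'
#' Projects the samples onto the first two principal components of centered
#' log-CPM - the standard before/after picture for batch-effect inspection:
#' with a strong batch effect the leading component separates batches rather
#' than biological conditions. Component signs are fixed (largest-magnitude
#' loading positive) so the output is deterministic.
#'
#' @inheritParams residual_matrix
#' @param n_components number of components to return (default 2; must not
#'   exceed samples).
#' @return data frame of sample scores with one column per component, plus
#'   attribute \code{"var_explained"} (proportion of variance per
#'   component).
#' @export
pca_diagnostic <- function(counts, prior_count = 2, n_components = 2) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 3L) stop("at least 3 samples are required")
  if (n_components > ncol(counts))
    stop("more components requested than samples")
  lc <- logcpm_transform(counts, prior_count = prior_count)
  pc <- prcomp(t(lc), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    top <- which.max(abs(rot[, j]))
    if (rot[top, j] < 0) scores[, j] <- -scores[, j]
  }
  out <- as.data.frame(scores)
  rownames(out) <- colnames(counts)
  attr(out, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  out
}
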