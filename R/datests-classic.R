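#' Log2 counts-per-million with a library-size-scaled prior count
#'
#' Transforms raw counts to \code{log2} CPM after adding a pseudo-count that
#' is scaled proportionally to each sample's library size relative to the
#' mean library size:
#' \deqn{\log_2\left(\frac{y + p_j}{L_j + 2 p_j} \cdot 10^6\right), \quad
#'       p_j = p \cdot L_j / \bar L.}
#' Zero counts therefore map to a finite value, and the transform agrees with
#' the widely used log-CPM convention for count matrices.
#'
#' @param counts non-negative count matrix (peaks x samples).
#' @param lib_sizes library sizes (default: column sums; must be > 0).
#' @param prior_count pseudo-count \code{p} (default 2).
#' @return real matrix of the same shape as \code{counts}.
#' @export
logcpm_transform <- function(counts, lib_sizes = colSums(counts),
                             prior_count = 2) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(lib_sizes) != ncol(counts))
    stop("one library size per sample is required")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  pr <- prior_count * lib_sizes / mean(lib_sizes)
  log2(t((t(counts) + pr) / (lib_sizes + 2 * pr)) * 1e6)
}

## Inverse of logcpm_transform, used when corrected log-CPM values have to be
## written back as counts.
inverse_logcpm <- function(values, lib_sizes, prior_count = 2) {
  pr <- prior_count * lib_sizes / mean(lib_sizes)
  t(t(2^values) / 1e6 * (lib_sizes + 2 * pr) - pr)
}

check_groups <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("exactly two groups are required")
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 samples")
  if (length(groups) != ncol(values))
    stop("one group label per column is required")
  groups
}

new_da_result <- function(peak_id, log2fc, statistic, pvalue, method) {
  pvalue <- pmin(pmax(pvalue, 0), 1)
  structure(data.frame(peak_id = peak_id, log2fc = log2fc,
                       statistic = statistic, pvalue = pvalue,
                       padj = bh_adjust(pvalue), stringsAsFactors = FALSE),
            method = method, class = c("da_result", "data.frame"))
}

#' @export
print.da_result <- function(x, ...) {
  cat(sprintf("Differential accessibility results (%s): %d peaks, %d at BH < 0.05\n",
              attr(x, "method"), nrow(x), sum(x$padj < 0.05)))
  print(head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

row_fc <- function(values, ga, gb) {
  rowMeans(values[, ga, drop = FALSE]) - rowMeans(values[, gb, drop = FALSE])
}

#' Two-sided Wilcoxon rank-sum test, row-wise
#'
#' Vectorized rank-sum test across the rows of a matrix. For rows without
#' ties and total sample size at most 25 the exact conditional null
#' distribution of the rank-sum statistic is used; otherwise the normal
#' approximation with tie correction and continuity correction is applied
#' (matching the classical two-sided rank-sum test). With three replicates
#' per group the smallest attainable p-value is 2/C(6,3) = 0.1, which is why
#' the rank-sum test has no power at genome-wide FDR cut-offs in small
#' designs.
#'
#' @param values real matrix (peaks x samples), typically log2-CPM.
#' @param groups two-level factor over the columns; the first level is the
#'   "A" side of the reported fold change.
#' @return a \code{"da_result"} data frame: \code{peak_id}, \code{log2fc}
#'   (difference of group mean values), \code{statistic} (the Mann-Whitney U
#'   for group A), \code{pvalue}, \code{padj} (Benjamini-Hochberg).
#' @export
wilcoxon_test <- function(values, groups) {
  values <- as.matrix(values)
  groups <- check_groups(values, groups)
  ga <- which(groups == levels(groups)[1])
  gb <- which(groups == levels(groups)[2])
  n1 <- length(ga); n2 <- length(gb); n <- n1 + n2
  a <- values[, ga, drop = FALSE]
  b <- values[, gb, drop = FALSE]
  ## Mann-Whitney U for group A plus cross-group tie mass, in one pass over
  ## the n1 x n2 pairs (vectorized over peaks).
  u <- numeric(nrow(values)); tied <- logical(nrow(values))
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    eq <- a[, i] == b[, j]
    u <- u + (a[, i] > b[, j]) + 0.5 * eq
    tied <- tied | eq
  }
  ## Within-group ties also invalidate the exact distribution.
  if (n1 > 1) for (i in seq_len(n1 - 1)) for (j in (i + 1):n1)
    tied <- tied | (a[, i] == a[, j])
  if (n2 > 1) for (i in seq_len(n2 - 1)) for (j in (i + 1):n2)
    tied <- tied | (b[, i] == b[, j])

  p <- rep(NA_real_, nrow(values))
  exact_ok <- !tied & n <= 25
  if (any(exact_ok)) {
    ue <- u[exact_ok]
    upper <- ue > n1 * n2 / 2
    pe <- numeric(length(ue))
    pe[upper] <- 2 * (1 - pwilcox(ue[upper] - 1, n1, n2))
    pe[!upper] <- 2 * pwilcox(ue[!upper], n1, n2)
    p[exact_ok] <- pmin(pe, 1)
  }
  if (any(!exact_ok)) {
    mu <- n1 * n2 / 2
    ## Tie-free rows outside the exact range: plain normal approximation,
    ## vectorized (the tie correction term vanishes).
    plain <- !exact_ok & !tied
    if (any(plain)) {
      z <- u[plain] - mu
      z <- (z - sign(z) * 0.5) / sqrt(n1 * n2 * (n + 1) / 12)
      p[plain] <- pmin(1, 2 * pnorm(-abs(z)))
    }
    idx <- which(!exact_ok & tied)
    for (g in idx) {
      tab <- table(values[g, c(ga, gb)])
      sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
      if (sigma2 <= 0) { p[g] <- 1; next }
      z <- u[g] - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
      p[g] <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  new_da_result(rownames(values) %||% seq_len(nrow(values)),
                row_fc(values, ga, gb), u, p, "wilcoxon")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-sided two-sample t-test, row-wise
#'
#' Vectorized two-sample t-test across the rows of a matrix. The default is
#' the Welch form (unequal variances, Satterthwaite degrees of freedom),
#' which is the usual default of interactive two-sample t-tests;
#' \code{var_equal = TRUE} gives the pooled-variance form with
#' \code{n1 + n2 - 2} degrees of freedom. Rows with zero variance in both
#' groups get p = 1 when the means are equal; when the means differ the
#' smallest representable positive p-value is reported (and the statistic is
#' infinite) so that downstream BH adjustment and log-scale plots stay
#' finite.
#'
#' @inheritParams wilcoxon_test
#' @param var_equal pool the two group variances? Default \code{FALSE}
#'   (Welch).
#' @return a \code{"da_result"} data frame (see [wilcoxon_test()]).
#' @export
student_t_test <- function(values, groups, var_equal = FALSE) {
  values <- as.matrix(values)
  groups <- check_groups(values, groups)
  ga <- which(groups == levels(groups)[1])
  gb <- which(groups == levels(groups)[2])
  n1 <- length(ga); n2 <- length(gb)
  a <- values[, ga, drop = FALSE]; b <- values[, gb, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (n1 - 1)
  vb <- rowSums((b - mb)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * va + (n2 - 1) * vb) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  } else {
    se2 <- va / n1 + vb / n2
    df <- se2^2 / ((va / n1)^2 / (n1 - 1) + (vb / n2)^2 / (n2 - 1))
  }
  tstat <- (ma - mb) / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    same <- degenerate & (ma == mb)
    tstat[same] <- 0; p[same] <- 1
    flip <- degenerate & (ma != mb)
    tstat[flip] <- sign(ma - mb)[flip] * Inf
    p[flip] <- .Machine$double.xmin
    if (any(flip))
      warning(sum(flip), " peak(s) with zero variance but differing means; ",
              "smallest representable p reported")
  }
  res <- new_da_result(rownames(values) %||% seq_len(nrow(values)),
                       ma - mb, tstat, p, "ttest")
  res$df <- df
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' ascending, \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, returned in the
#' original order and capped at 1. Input order does not affect the adjusted
#' values. This is the standard BH procedure as provided by
#' \code{stats::p.adjust}; inputs are validated so that NaN or out-of-range
#' values fail loudly instead of propagating.
#'
#' @param pvalues numeric vector of raw p-values in \code{[0, 1]}.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)))
    stop("NaN/NA p-values are not allowed")
  if (any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}
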