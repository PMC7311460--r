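## Conditional log-likelihood of the common dispersion given the group sums,
## under equal library sizes: for a group of n replicates with counts y and
## sum z, l(phi) = sum_i lgamma(y_i + r) + lgamma(n r) - lgamma(z + n r)
## - n lgamma(r), with r = 1/phi. Summed over peaks and both groups.
common_dispersion_cll <- function(phi, counts, group_idx) {
  r <- 1 / phi
  ll <- 0
  for (idx in group_idx) {
    n <- length(idx)
    y <- counts[, idx, drop = FALSE]
    z <- rowSums(y)
    ll <- ll + sum(lgamma(y + r)) + nrow(counts) * (lgamma(n * r) -
      n * lgamma(r)) - sum(lgamma(z + n * r))
  }
  ll
}

#' Common dispersion by conditional maximum likelihood
#'
#' Estimates a single negative-binomial dispersion shared by all peaks by
#' maximizing the conditional likelihood of the within-group counts given
#' the group sums, assuming (near-)equal library sizes. The maximization is
#' over \code{log(phi)} with \code{optimize()}.
#'
#' @param counts non-negative integer matrix (peaks x samples).
#' @param groups two-level factor over the columns.
#' @param interval search interval for the dispersion.
#' @return the estimated dispersion (phi; variance = mu + phi mu^2).
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       interval = c(1e-6, 5)) {
  groups <- check_groups(counts, groups)
  group_idx <- lapply(levels(groups), function(l) which(groups == l))
  ## Drop all-zero peaks: they carry no dispersion information.
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  opt <- optimize(function(lphi)
    common_dispersion_cll(exp(lphi), counts, group_idx),
    interval = log(interval), maximum = TRUE, tol = 1e-6)
  exp(opt$maximum)
}

## Double-tail exact p-value for one total T: the conditional distribution of
## group A's sum k given the total is negative hypergeometric,
##   f(k) proportional to C(k + r1 - 1, k) C(T - k + r2 - 1, T - k),
## independent of the NB mean (the probability parameter cancels). Returns
## p(k) for k = 0..T: the sum of probabilities of outcomes as or less likely
## than k.
nb_exact_tail <- function(total, r1, r2) {
  k <- 0:total
  ## log C(k + r - 1, k) up to the r-only constant, via the rising
  ## factorial: sum_{i < k} log(r + i) - lgamma(k + 1). Unlike lgamma(k + r)
  ## this keeps full precision when r is huge (the dispersion -> 0 limit).
  rise1 <- c(0, cumsum(log(r1 + 0:max(total - 1, 0))))
  rise2 <- c(0, cumsum(log(r2 + 0:max(total - 1, 0))))
  logf <- rise1[k + 1] - lgamma(k + 1) + rise2[total - k + 1] -
    lgamma(total - k + 1)
  logf <- logf - max(logf)
  f <- exp(logf)
  f <- f / sum(f)
  ord <- order(f)
  fs <- f[ord]
  csum <- cumsum(fs)
  ## Outcomes as or less likely than the observed one, with the customary
  ## (1 + 1e-7) relative slack so numerically tied probabilities share one
  ## tail mass (order-invariant, and the convention of exact double-tail
  ## tests).
  idx <- findInterval(fs * (1 + 1e-7), fs)
  out <- numeric(total + 1)
  out[ord] <- pmin(csum[idx], 1)
  out
}

#' Negative-binomial exact test with common dispersion
#'
#' Two-sided exact test for a difference in mean counts between two groups,
#' assuming negative-binomial counts with a shared dispersion and
#' (near-)equal library sizes. Under these assumptions the sum of a group's
#' counts is itself negative binomial, and the conditional distribution of
#' one group's sum given the peak total does not depend on the mean - so
#' peaks sharing a total share the entire null distribution, and the
#' genome-wide test costs one tail computation per *distinct* total. The
#' p-value is the total probability of outcomes as or less likely than the
#' observed split (the double-tail rule); an all-zero peak has a single
#' attainable outcome and p = 1.
#'
#' @param counts non-negative integer matrix (peaks x samples).
#' @param groups two-level factor over the columns.
#' @param dispersion_mode \code{"common"} (conditional-ML shared dispersion)
#'   or \code{"per_peak_moment"} (method-of-moments dispersion per peak,
#'   pooled across the two groups).
#' @param dispersion optional fixed dispersion, bypassing estimation (e.g.
#'   a value near 0 gives the binomial/Poisson limit).
#' @param prior_count pseudo-count for the reported log2 fold change (the
#'   fold change is the difference of group mean log2-CPM, as for the other
#'   methods).
#' @return a \code{"da_result"} data frame (see [wilcoxon_test()]); the
#'   dispersion used is attached as attribute \code{"dispersion"}.
#' @export
nb_exact_test <- function(counts, groups,
                          dispersion_mode = c("common", "per_peak_moment"),
                          dispersion = NULL, prior_count = 2) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  dispersion_mode <- match.arg(dispersion_mode)
  groups <- check_groups(counts, groups)
  ga <- which(groups == levels(groups)[1])
  gb <- which(groups == levels(groups)[2])
  n1 <- length(ga); n2 <- length(gb)
  s1 <- rowSums(counts[, ga, drop = FALSE])
  total <- s1 + rowSums(counts[, gb, drop = FALSE])

  p <- rep(NA_real_, nrow(counts))
  if (dispersion_mode == "common" || !is.null(dispersion)) {
    phi <- if (!is.null(dispersion)) dispersion
           else estimate_common_dispersion(counts, groups)
    r1 <- n1 / phi; r2 <- n2 / phi
    by_total <- split(seq_along(total), total)
    for (key in names(by_total)) {
      rows <- by_total[[key]]
      tt <- total[rows[1L]]
      if (tt == 0) { p[rows] <- 1; next }
      tail_p <- nb_exact_tail(tt, r1, r2)
      p[rows] <- tail_p[s1[rows] + 1L]
    }
  } else {
    mu <- total / (n1 + n2)
    v <- (rowSums((counts[, ga, drop = FALSE] - s1 / n1)^2) +
          rowSums((counts[, gb, drop = FALSE] - (total - s1) / n2)^2)) /
         (n1 + n2 - 2)
    phi_g <- pmax((v - mu) / mu^2, 1e-8)
    phi_g[!is.finite(phi_g)] <- 1e-8
    phi <- phi_g
    for (g in seq_len(nrow(counts))) {
      if (total[g] == 0) { p[g] <- 1; next }
      tail_p <- nb_exact_tail(total[g], n1 / phi_g[g], n2 / phi_g[g])
      p[g] <- tail_p[s1[g] + 1L]
    }
  }
  lc <- logcpm_transform(counts, prior_count = prior_count)
  res <- new_da_result(rownames(counts) %||% seq_len(nrow(counts)),
                       row_fc(lc, ga, gb), s1, p, "nb_exact")
  attr(res, "dispersion") <- phi
  res
}
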