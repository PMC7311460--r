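## Invert the trigamma function by Newton iteration (tol 1e-8 on the
## argument, at most 50 iterations). Used to moment-match the prior degrees
## of freedom of the variance distribution.
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in seq_len(50L)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < 1e-8) break
  }
  x
}

## Moment-match a scaled-F distribution to the per-peak sample variances:
## estimate the prior degrees of freedom d0 and prior variance s0^2 from the
## distribution of log variances (Smyth-style). Zero variances are excluded
## from the fit.
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 2L) return(list(df_prior = Inf, var_prior = mean(s2[ok])))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior <- exp(mean(e))
  }
  list(df_prior = df_prior, var_prior = var_prior)
}

#' Moderated t-test with empirical-Bayes variance shrinkage
#'
#' Fits a per-peak linear model of the (log-CPM) values on the condition,
#' optionally adjusting for a batch covariate, and moderates the residual
#' variances by shrinking them toward a common prior estimated from all
#' peaks: the posterior variance is
#' \deqn{\tilde s^2_g = \frac{d_0 s_0^2 + d s_g^2}{d_0 + d},}
#' with the prior degrees of freedom \eqn{d_0} and prior variance
#' \eqn{s_0^2} obtained by moment-matching the distribution of log residual
#' variances (a Newton inversion of the trigamma function, tolerance 1e-8).
#' The moderated t-statistic has \eqn{d_0 + d} degrees of freedom. In the
#' \eqn{d_0 = 0} limit this is the ordinary pooled-variance t-test; in the
#' \eqn{d_0 = \infty} limit every peak is tested against the common variance
#' \eqn{s_0^2}.
#'
#' Optional precision weights (\code{voom_weights = TRUE}) are derived from a
#' smoothed mean-variance trend: a lowess fit of the quarter-root residual
#' standard deviations against mean log2 counts, inverted at the fitted
#' per-observation values; each peak is then refit by weighted least squares.
#'
#' @inheritParams wilcoxon_test
#' @param batch optional factor of batch labels over the columns, included
#'   as covariates ahead of the condition effect.
#' @param voom_weights use mean-variance precision weights? Default
#'   \code{FALSE}.
#' @param counts raw counts, required when \code{voom_weights = TRUE} (the
#'   trend's x-axis is the mean log2 count).
#' @param prior_df override the estimated prior degrees of freedom
#'   \eqn{d_0} (mainly for studying the shrinkage limits; \code{0} disables
#'   shrinkage, \code{Inf} forces complete shrinkage).
#' @return a \code{"da_result"} data frame (see [wilcoxon_test()]); the
#'   estimated \code{df_prior} and \code{var_prior} are attached as
#'   attributes.
#' @export
moderated_t_test <- function(values, groups, batch = NULL,
                             voom_weights = FALSE, counts = NULL,
                             prior_df = NULL) {
  values <- as.matrix(values)
  groups <- check_groups(values, groups)
  n <- ncol(values)
  design <- if (is.null(batch)) model.matrix(~ groups)
            else model.matrix(~ factor(batch) + groups)
  if (qr(design)$rank < ncol(design))
    stop("design matrix is rank deficient")
  coef_idx <- ncol(design)          # the condition effect (level 2 vs 1)
  df_resid <- n - ncol(design)
  if (df_resid < 1L) stop("no residual degrees of freedom")

  xtxi <- chol2inv(chol(crossprod(design)))
  beta <- values %*% design %*% xtxi            # peaks x p
  fitted <- beta %*% t(design)
  resid <- values - fitted
  s2 <- rowSums(resid^2) / df_resid
  unscaled <- xtxi[coef_idx, coef_idx]

  if (voom_weights) {
    if (is.null(counts)) stop("'counts' is required for voom-style weights")
    lib <- colSums(counts)
    xbar <- rowMeans(logcpm_transform(counts, lib, 0.5)) +
      mean(log2(lib + 1)) - log2(1e6)
    sq <- sqrt(sqrt(s2))
    lo <- lowess(xbar, sq, f = 0.5)
    ## Per-observation x: fitted log-CPM shifted to each sample's log depth.
    w <- matrix(0, nrow(values), n)
    shift <- log2(lib + 1) - log2(1e6)
    for (j in seq_len(n)) {
      xj <- fitted[, j] + shift[j] - mean(shift)
      sdq <- approx(lo$x, lo$y, xout = xj, rule = 2, ties = mean)$y
      w[, j] <- 1 / pmax(sdq, 1e-4)^4
    }
    ## Weighted refit, peak by peak.
    for (g in seq_len(nrow(values))) {
      wg <- w[g, ]
      xtw <- t(design * wg)
      xtxi_g <- chol2inv(chol(xtw %*% design))
      bg <- xtxi_g %*% (xtw %*% values[g, ])
      rg <- values[g, ] - design %*% bg
      beta[g, ] <- bg
      s2[g] <- sum(wg * rg^2) / df_resid
      if (g == 1L) unscaled <- numeric(nrow(values))
      unscaled[g] <- xtxi_g[coef_idx, coef_idx]
    }
  }

  prior <- if (is.null(prior_df)) fit_variance_prior(s2, df_resid)
           else list(df_prior = prior_df,
                     var_prior = fit_variance_prior(s2, df_resid)$var_prior)
  d0 <- prior$df_prior
  s2_post <- if (is.infinite(d0)) rep(prior$var_prior, length(s2))
             else (d0 * prior$var_prior + df_resid * s2) / (d0 + df_resid)
  tstat <- -beta[, coef_idx] / sqrt(s2_post * unscaled)  # A minus B
  df_total <- min(d0 + df_resid, .Machine$double.xmax)
  p <- 2 * pt(-abs(tstat), df_total)
  ga <- which(groups == levels(groups)[1])
  gb <- which(groups == levels(groups)[2])
  res <- new_da_result(rownames(values) %||% seq_len(nrow(values)),
                       row_fc(values, ga, gb), tstat, p, "moderated_t")
  attr(res, "df_prior") <- d0
  attr(res, "var_prior") <- prior$var_prior
  res
}
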