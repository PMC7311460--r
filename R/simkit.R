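#' Resolve the two condition means for a peak
#'
#' Given a tier's nominal density and a relative mean difference, returns the
#' low- and high-condition mean densities such that (1) the two condition
#' means average to the nominal density and (2) the high condition exceeds the
#' low condition by the stated fraction. In closed form,
#' \code{low = 2 * nominal / (2 + f)} and \code{high = low * (1 + f)}.
#'
#' For example, a 5 CPM peak with a 50\% mean difference resolves to 4 CPM
#' (low) and 6 CPM (high): their average is 5 and 6 is 50\% more than 4.
#'
#' @param nominal_cpm nominal tier density in counts per million (> 0).
#'   Vectorized.
#' @param mean_diff_fraction relative excess of the high condition over the
#'   low condition (>= 0; 0 means no difference). Vectorized.
#' @return a list with numeric components \code{low} and \code{high} (CPM).
#' @examples
#' resolve_condition_means(5, 0.5)   # low = 4, high = 6
#' resolve_condition_means(1, 1)     # low = 2/3, high = 4/3
#' @export
resolve_condition_means <- function(nominal_cpm, mean_diff_fraction) {
  if (any(!is.finite(nominal_cpm)) || any(nominal_cpm <= 0))
    stop("'nominal_cpm' must be positive and finite")
  if (any(!is.finite(mean_diff_fraction)) || any(mean_diff_fraction < 0))
    stop("'mean_diff_fraction' must be non-negative and finite")
  low <- 2 * nominal_cpm / (2 + mean_diff_fraction)
  list(low = low, high = low * (1 + mean_diff_fraction))
}

#' Number of simulated peaks implied by a tier mix
#'
#' The simulator pins the expected total density at one million CPM so that
#' counts and sequencing depth stay consistent: with tier proportions
#' \eqn{p_t} and densities \eqn{c_t}, the peak count is
#' \eqn{N = \mathrm{round}(10^6 / \sum_t p_t c_t)}. The default design
#' (60\%/30\%/10\% at 1/5/10 CPM) gives 322,581 peaks.
#'
#' @param tiers data frame with columns \code{cpm} and \code{prop}, as in
#'   [simulation_design()].
#' @return integer peak count.
#' @export
compute_peak_count <- function(tiers) {
  tiers <- validate_tiers(tiers)
  round(1e6 / sum(tiers$prop * tiers$cpm))
}

validate_tiers <- function(tiers) {
  if (is.null(tiers) || NROW(tiers) == 0L) stop("tier list is empty")
  tiers <- as.data.frame(tiers)
  if (!all(c("cpm", "prop") %in% names(tiers)))
    stop("tiers need columns 'cpm' and 'prop'")
  if (any(tiers$cpm <= 0)) stop("tier densities must be positive")
  if (abs(sum(tiers$prop) - 1) > 1e-8) stop("tier proportions must sum to 1")
  tiers
}

validate_classes <- function(classes) {
  if (is.null(classes) || NROW(classes) == 0L) stop("class list is empty")
  classes <- as.data.frame(classes)
  if (!all(c("diff", "prop") %in% names(classes)))
    stop("classes need columns 'diff' and 'prop'")
  if (any(classes$diff < 0)) stop("mean-difference fractions must be >= 0")
  if (abs(sum(classes$prop) - 1) > 1e-8) stop("class proportions must sum to 1")
  classes
}

#' Describe one simulated ATAC-seq experiment
#'
#' Bundles every knob of the simulator: the tier mix (signal-density levels
#' and their proportions), the mean-difference classes (the 0 class is the
#' true-negative background), sequencing depth in effective reads under
#' peaks, the in-group standard deviation as a fraction of each condition's
#' mean, and the number of replicates generated per condition. Defaults
#' follow the benchmark design: 60/30/10\% of peaks at 1/5/10 CPM, 80\% true
#' negatives plus 5\% each at 10/20/50/100\% mean difference, 30 M effective
#' reads, 10\% in-group SD, and 20 replicates per condition (down-sampled
#' later by taking leading columns).
#'
#' @param tiers data frame with columns \code{cpm}, \code{prop}.
#' @param classes data frame with columns \code{diff}, \code{prop}; must
#'   include the 0 (true-negative) class.
#' @param depth effective reads under peaks (e.g. 10e6, 20e6, 30e6).
#' @param sd_fraction in-group SD as a fraction of each condition's own mean.
#' @param replicates replicates per condition (>= 2).
#' @param n_repeats number of independent simulated files in a sweep.
#' @param seed RNG seed for [simulate_counts()].
#' @param n_peaks optional override of the peak count; by default derived
#'   from the tier mix by [compute_peak_count()].
#' @return an object of class \code{"sim_design"}.
#' @export
simulation_design <- function(tiers = data.frame(cpm = c(1, 5, 10),
                                                 prop = c(0.6, 0.3, 0.1)),
                              classes = data.frame(diff = c(0, 0.1, 0.2, 0.5, 1),
                                                   prop = c(0.8, 0.05, 0.05, 0.05, 0.05)),
                              depth = 30e6,
                              sd_fraction = 0.10,
                              replicates = 20L,
                              n_repeats = 50L,
                              seed = 1L,
                              n_peaks = NULL) {
  tiers <- validate_tiers(tiers)
  classes <- validate_classes(classes)
  if (!is.numeric(depth) || depth <= 0) stop("'depth' must be positive")
  if (sd_fraction <= 0 || sd_fraction >= 1)
    stop("'sd_fraction' must be in (0, 1)")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 2L)
    stop("'replicates' must be an integer >= 2")
  if (is.null(n_peaks)) n_peaks <- compute_peak_count(tiers)
  structure(list(tiers = tiers, classes = classes, depth = depth,
                 sd_fraction = sd_fraction, replicates = replicates,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 n_peaks = as.integer(n_peaks)),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("Simulated ATAC-seq experiment design\n")
  cat(sprintf("  peaks: %d   depth: %g effective reads   in-group SD: %g%%\n",
              x$n_peaks, x$depth, 100 * x$sd_fraction))
  cat(sprintf("  replicates/condition: %d   repeats: %d   seed: %d\n",
              x$replicates, x$n_repeats, x$seed))
  cat("  tiers:  ", paste(sprintf("%g CPM (%g%%)", x$tiers$cpm,
                                  100 * x$tiers$prop), collapse = ", "), "\n")
  cat("  classes:", paste(sprintf("%g%% (%g%%)", 100 * x$classes$diff,
                                  100 * x$classes$prop), collapse = ", "), "\n")
  invisible(x)
}

## Largest-remainder-free exact allocation: cumulative rounding guarantees the
## group sizes sum exactly to n while each is within 1 of n * prop.
allocate_exact <- function(n, prop) {
  diff(round(cumsum(c(0, prop)) * n))
}

## Evaluate fun() under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards.
with_seed <- function(seed, fun) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

#' Simulate a labelled ATAC-seq peak-count matrix
#'
#' Generates one peaks-by-samples matrix of integer counts under a
#' [simulation_design()]. Peak tiers and mean-difference classes are allocated
#' deterministically in the design proportions (fixed counts, not sampled).
#' For each true-positive peak the two condition means are resolved by
#' [resolve_condition_means()]; directions alternate so that half of each
#' class is higher in condition A and half in condition B. Each replicate's
#' density is drawn from a normal distribution around its condition mean with
#' SD equal to \code{sd_fraction} times that mean, then converted to a count
#' as \code{round(cpm * depth / 1e6)} and clamped at zero (negative draws are
#' truncated, not redrawn).
#'
#' @param design a [simulation_design()].
#' @param seed RNG seed; defaults to the design's seed. The same seed always
#'   reproduces the same matrix.
#' @return an object of class \code{"peak_matrix"}: a list with
#'   \describe{
#'     \item{counts}{integer matrix, peaks x (2 * replicates), rownames are
#'       peak ids and colnames sample ids (\code{A1..An, B1..Bn}).}
#'     \item{condition}{factor of length 2n with levels \code{A}, \code{B}.}
#'     \item{truth}{data frame with \code{peak_id}, \code{tier_cpm},
#'       \code{mean_diff}, \code{direction} (+1 if condition A is the high
#'       condition, -1 if B, 0 for true negatives).}
#'     \item{design}{the generating design.}
#'   }
#' @export
simulate_counts <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "sim_design"))
  n_tier <- allocate_exact(design$n_peaks, design$tiers$prop)
  tier <- rep(design$tiers$cpm, n_tier)
  n_peaks <- length(tier)
  cls <- unlist(lapply(n_tier, function(n)
    rep(design$classes$diff, allocate_exact(n, design$classes$prop))),
    use.names = FALSE)
  ## Alternate +1/-1 within each tier x class cell; true negatives get 0.
  direction <- integer(n_peaks)
  cell <- interaction(tier, cls, drop = TRUE)
  direction <- as.integer(stats::ave(direction, cell,
                                     FUN = function(v) rep_len(c(1L, -1L), length(v))))
  direction[cls == 0] <- 0L

  means <- resolve_condition_means(tier, cls)
  mean_a <- ifelse(direction >= 0, means$high, means$low)
  mean_b <- ifelse(direction >= 0, means$low, means$high)
  ## For true negatives both branches coincide (low == high).
  n <- design$replicates
  counts <- with_seed(seed, function() {
    cpm_a <- matrix(rnorm(n_peaks * n, mean_a, design$sd_fraction * mean_a),
                    n_peaks, n)
    cpm_b <- matrix(rnorm(n_peaks * n, mean_b, design$sd_fraction * mean_b),
                    n_peaks, n)
    pmax(round(cbind(cpm_a, cpm_b) * design$depth / 1e6), 0)
  })
  peak_id <- sprintf("peak_%06d", seq_len(n_peaks))
  dimnames(counts) <- list(peak_id,
                           c(paste0("A", seq_len(n)), paste0("B", seq_len(n))))
  structure(list(counts = counts,
                 condition = factor(rep(c("A", "B"), each = n)),
                 truth = data.frame(peak_id = peak_id, tier_cpm = tier,
                                    mean_diff = cls, direction = direction,
                                    stringsAsFactors = FALSE),
                 design = design),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("Simulated peak-count matrix: %d peaks x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  depth %g, in-group SD %g%%, %d true-positive peaks\n",
              x$design$depth, 100 * x$design$sd_fraction,
              sum(x$truth$mean_diff > 0)))
  invisible(x)
}

#' Keep the first k replicates per condition
#'
#' Down-samples a simulated matrix by taking the leading \code{k} replicate
#' columns of each condition, mirroring the down-sampling protocol used in
#' replicate sweeps. With \code{sample_seed} set, a random subset of columns
#' per condition is taken instead.
#'
#' @param x a \code{"peak_matrix"}.
#' @param k replicates per condition to keep (2 <= k <= generated).
#' @param sample_seed optional seed for random (rather than prefix) selection.
#' @return a \code{"peak_matrix"} with 2k samples.
#' @export
subset_replicates <- function(x, k, sample_seed = NULL) {
  stopifnot(inherits(x, "peak_matrix"))
  n <- sum(x$condition == levels(x$condition)[1])
  k <- as.integer(k)
  if (k < 2L || k > n) stop("'k' must be between 2 and ", n)
  pick <- function(idx) {
    if (is.null(sample_seed)) idx[seq_len(k)]
    else with_seed(sample_seed, function() sort(sample(idx, k)))
  }
  keep <- c(pick(which(x$condition == "A")), pick(which(x$condition == "B")))
  out <- x
  out$counts <- x$counts[, keep, drop = FALSE]
  out$condition <- factor(x$condition[keep])
  out
}

#' Inject a multiplicative batch effect into a simulated matrix
#'
#' Scales the counts of every sample outside the reference batch by a
#' peak-specific log-normal factor with median \code{effect_size} (log-scale
#' SD equal to half \code{|log(effect_size)|}, so an effect size of 1 leaves
#' the matrix unchanged). Truth labels are untouched; the injected variation
#' is "unwanted" by construction and serves as a fixture for factor-based
#' correction.
#'
#' @param x a \code{"peak_matrix"}.
#' @param batch factor (or vector) assigning every sample to a batch; the
#'   first level is the unaffected reference. Named vectors are matched to
#'   sample ids.
#' @param effect_size multiplicative batch effect (> 0).
#' @param seed RNG seed for the peak-specific factors.
#' @return a \code{"peak_matrix"} with an added \code{batch} factor.
#' @export
batch_inject <- function(x, batch, effect_size = 1.5, seed = 1L) {
  stopifnot(inherits(x, "peak_matrix"))
  if (!is.null(names(batch))) {
    miss <- setdiff(names(batch), colnames(x$counts))
    if (length(miss)) stop("unknown sample id: ", paste(miss, collapse = ", "))
    batch <- batch[colnames(x$counts)]
  }
  if (length(batch) != ncol(x$counts))
    stop("every sample needs a batch assignment")
  if (!is.numeric(effect_size) || effect_size <= 0)
    stop("'effect_size' must be positive")
  batch <- factor(batch)
  affected <- batch != levels(batch)[1]
  out <- x
  if (any(affected) && effect_size != 1) {
    sdlog <- abs(log(effect_size)) / 2
    fac <- with_seed(seed, function()
      exp(rnorm(nrow(x$counts), log(effect_size), sdlog)))
    out$counts[, affected] <- pmax(round(x$counts[, affected, drop = FALSE] * fac), 0)
  }
  out$batch <- batch
  out
}
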