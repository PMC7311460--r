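test_that("log-CPM transform matches direct arithmetic and stays finite", {
  # count 100, library 1e6, prior 2, equal library sizes
  cnt <- matrix(c(100, 50, 30, 70), 2, 2)
  v <- logcpm_transform(cnt, lib_sizes = c(1e6, 1e6), prior_count = 2)
  expect_equal(v[1, 1], log2(102 / 1000004 * 1e6), tolerance = 1e-12)
  expect_equal(v[1, 1], 6.6724, tolerance = 1e-4)
  # zero counts map to a finite value
  z <- logcpm_transform(matrix(c(0, 5), 1), lib_sizes = c(1000, 1000))
  expect_true(all(is.finite(z)))
  # global scaling enters only through the prior term
  cnt2 <- cnt * 2
  v_small <- logcpm_transform(cnt, lib_sizes = c(1e6, 1e6), prior_count = 1e-9)
  v2_small <- logcpm_transform(cnt2, lib_sizes = c(2e6, 2e6), prior_count = 1e-9)
  expect_equal(v_small, v2_small, tolerance = 1e-7)
  expect_error(logcpm_transform(cnt, lib_sizes = c(0, 1e6)), "positive")
})

test_that("log-CPM transform agrees with the edgeR cpm convention", {
  skip_if_not_installed("edgeR")
  set.seed(1)
  cnt <- matrix(rpois(200, 40), 50, 4,
                dimnames = list(paste0("p", 1:50), paste0("s", 1:4)))
  ours <- logcpm_transform(cnt, prior_count = 2)
  theirs <- edgeR::cpm(cnt, log = TRUE, prior.count = 2)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
})

test_that("rank-sum test reproduces exact small-sample p-values", {
  # complete separation, 3 vs 3: p = 2 / C(6,3) = 0.1
  v <- matrix(c(1, 2, 3, 10, 11, 12), 1)
  g <- factor(rep(c("A", "B"), each = 3))
  expect_equal(wilcoxon_test(v, g)$pvalue, 0.1)
  # complete separation, 5 vs 5: p = 2 / C(10,5)
  v5 <- matrix(c(1:5, 11:15), 1)
  g5 <- factor(rep(c("A", "B"), each = 5))
  expect_equal(wilcoxon_test(v5, g5)$pvalue, 2 / 252)
  # identical values in both groups: tie path, p = 1
  expect_equal(wilcoxon_test(matrix(rep(2, 6), 1), g)$pvalue, 1)
  expect_error(wilcoxon_test(matrix(1:4, 1), factor(c("A", "A", "A", "B"))),
               "at least 2")
})

test_that("rank-sum p-values agree with full labeling enumeration", {
  set.seed(33)
  for (ns in list(c(3, 3), c(4, 3), c(5, 5), c(4, 6))) {
    vals <- matrix(rnorm(10 * sum(ns)), 10)
    g <- factor(rep(c("A", "B"), ns))
    res <- wilcoxon_test(vals, g)
    brute <- apply(vals, 1, function(row)
      enumerate_wilcoxon_p(row[seq_len(ns[1])], row[-seq_len(ns[1])]))
    expect_equal(res$pvalue, unname(brute), tolerance = 1e-12)
  }
})

test_that("rank-sum test matches wilcox.test on exact and tied paths", {
  set.seed(12)
  vals <- matrix(rnorm(40 * 8), 40)
  vals[1:5, ] <- matrix(sample(1:3, 40, TRUE), 5)   # heavy ties
  g <- factor(rep(c("A", "B"), each = 4))
  res <- wilcoxon_test(vals, g)
  ref <- apply(vals, 1, function(row)
    suppressWarnings(stats::wilcox.test(row[1:4], row[5:8])$p.value))
  expect_equal(res$pvalue, unname(ref), tolerance = 1e-10)
  # large-sample path (n > 25): normal approximation as in wilcox.test
  g13 <- factor(rep(c("A", "B"), each = 13))
  vals26 <- matrix(rnorm(20 * 26), 20)
  res26 <- wilcoxon_test(vals26, g13)
  ref26 <- apply(vals26, 1, function(row)
    stats::wilcox.test(row[1:13], row[14:26], exact = FALSE,
                       correct = TRUE)$p.value)
  expect_equal(res26$pvalue, unname(ref26), tolerance = 1e-10)
})

test_that("t-test reproduces hand-computed and degenerate cases", {
  g <- factor(rep(c("A", "B"), each = 3))
  # {1,2,3} vs {4,5,6}: pooled SD 1, t = -3/sqrt(2/3)
  v <- matrix(c(1, 2, 3, 4, 5, 6), 1)
  res <- student_t_test(v, g, var_equal = TRUE)
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(res$pvalue, 0.02131, tolerance = 1e-4)
  # equal group variances: Welch coincides with pooled here
  expect_equal(student_t_test(v, g)$pvalue, res$pvalue, tolerance = 1e-12)
  # equal means: t = 0, p = 1
  expect_equal(student_t_test(matrix(c(1, 2, 3, 3, 2, 1), 1), g)$pvalue, 1)
  # scale invariance
  expect_equal(student_t_test(v * 2, g)$pvalue, student_t_test(v, g)$pvalue)
  # zero variance, differing means: flagged smallest representable p
  expect_warning(res0 <- student_t_test(matrix(c(1, 1, 1, 2, 2, 2), 1), g),
                 "zero variance")
  expect_equal(res0$pvalue, .Machine$double.xmin)
  # zero variance, equal means: p = 1
  expect_equal(suppressWarnings(
    student_t_test(matrix(rep(1, 6), 1), g)$pvalue), 1)
})

test_that("t-test matches t.test row by row in both variance modes", {
  set.seed(4)
  vals <- matrix(rnorm(30 * 9, sd = rep(c(1, 3), length.out = 30)), 30)
  g <- factor(rep(c("A", "B"), c(4, 5)))
  for (ve in c(TRUE, FALSE)) {
    res <- student_t_test(vals, g, var_equal = ve)
    ref <- apply(vals, 1, function(row)
      stats::t.test(row[1:4], row[5:9], var.equal = ve)$p.value)
    expect_equal(res$pvalue, unname(ref), tolerance = 1e-10)
  }
})

test_that("BH adjustment follows the step-up rule and its invariances", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  # step-up by hand: q_i = min_{j >= i} p_j m / j
  m <- length(p)
  hand <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(bh_adjust(p), hand)
  # adjusted never below raw, non-decreasing in raw rank
  expect_true(all(bh_adjust(p) >= p))
  expect_true(!is.unsorted(bh_adjust(p)))
  # permutation equivariance
  set.seed(2)
  perm <- sample(m)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  expect_error(bh_adjust(c(0.1, NaN)), "NaN")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("moderated t recovers its shrinkage limits", {
  set.seed(9)
  vals <- matrix(rnorm(80 * 6, sd = runif(80, 0.5, 2)), 80)
  g <- factor(rep(c("A", "B"), each = 3))
  # d0 = 0: ordinary pooled-variance t
  m0 <- moderated_t_test(vals, g, prior_df = 0)
  t0 <- student_t_test(vals, g, var_equal = TRUE)
  expect_equal(m0$pvalue, t0$pvalue, tolerance = 1e-10)
  expect_equal(m0$statistic, t0$statistic, tolerance = 1e-10)
  # d0 = Inf: every peak tested against the common variance
  minf <- moderated_t_test(vals, g, prior_df = Inf)
  s0 <- attr(minf, "var_prior")
  ga <- 1:3; gb <- 4:6
  tref <- (rowMeans(vals[, ga]) - rowMeans(vals[, gb])) / sqrt(s0 * (2 / 3))
  expect_equal(minf$statistic, tref, tolerance = 1e-10)
  expect_error(moderated_t_test(vals, g, batch = rep(c("A", "B"), each = 3)),
               "rank deficient")
})

test_that("moderated t agrees with the limma empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  set.seed(14)
  vals <- matrix(rnorm(200 * 8, sd = sqrt(1 / rgamma(200, 4, 4))), 200)
  g <- factor(rep(c("A", "B"), each = 4))
  ours <- moderated_t_test(vals, g)
  design <- stats::model.matrix(~ g)
  fit <- limma::eBayes(limma::lmFit(vals, design))
  expect_equal(attr(ours, "df_prior"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(ours, "var_prior"), fit$s2.prior, tolerance = 1e-6)
  # limma's coefficient is B - A; ours is A - B
  expect_equal(ours$statistic, -unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(ours$pvalue, unname(fit$p.value[, 2]), tolerance = 1e-8)
  # batch covariate changes the fit but keeps the contrast estimable
  batch <- factor(rep(c("x", "y"), 4))
  wb <- moderated_t_test(vals, g, batch = batch)
  fitb <- limma::eBayes(limma::lmFit(vals, stats::model.matrix(~ batch + g)))
  expect_equal(wb$pvalue, unname(fitb$p.value[, 3]), tolerance = 1e-8)
})

test_that("NB exact test collapses to the binomial test as dispersion vanishes", {
  set.seed(21)
  g <- factor(rep(c("A", "B"), each = 3))
  cnt <- matrix(rpois(50 * 6, 12), 50, 6)
  res <- nb_exact_test(cnt, g, dispersion = 1e-8)
  s1 <- rowSums(cnt[, 1:3]); tot <- rowSums(cnt)
  ref <- vapply(seq_len(nrow(cnt)), function(i)
    stats::binom.test(s1[i], tot[i], 0.5)$p.value, 0)
  expect_equal(res$pvalue, ref, tolerance = 1e-6)
  # unequal group sizes change the conditional null proportion
  g23 <- factor(rep(c("A", "B"), c(2, 3)))
  cnt5 <- cnt[, 1:5]
  res23 <- nb_exact_test(cnt5, g23, dispersion = 1e-8)
  s1 <- rowSums(cnt5[, 1:2]); tot <- rowSums(cnt5)
  ref23 <- vapply(seq_len(nrow(cnt5)), function(i)
    stats::binom.test(s1[i], tot[i], 2 / 5)$p.value, 0)
  expect_equal(res23$pvalue, ref23, tolerance = 1e-6)
})

test_that("NB exact test handles symmetric and degenerate splits", {
  g <- factor(rep(c("A", "B"), each = 3))
  # perfectly balanced group sums: the observed split is the mode, p = 1
  cnt <- matrix(c(5, 5, 5, 5, 5, 5,
                  0, 0, 0, 0, 0, 0), 2, 6, byrow = TRUE)
  res <- nb_exact_test(cnt, g, dispersion = 0.1)
  expect_equal(res$pvalue, c(1, 1))
  expect_error(nb_exact_test(matrix(c(1.5, 2, 2, 2, 2, 2), 1), g),
               "non-negative integers")
})

test_that("NB exact test matches edgeR's exact test at a fixed dispersion", {
  skip_if_not_installed("edgeR")
  set.seed(31)
  g <- factor(rep(c("A", "B"), each = 4))
  cnt <- matrix(rnbinom(300 * 8, mu = 30, size = 10), 300, 8)
  # equalize library sizes so both implementations share the conditional model
  cnt[1, ] <- cnt[1, ] + max(colSums(cnt)) - colSums(cnt)
  phi <- 0.1
  ours <- nb_exact_test(cnt, g, dispersion = phi)
  dge <- edgeR::DGEList(counts = cnt, group = g)
  dge$common.dispersion <- phi
  theirs <- edgeR::exactTest(dge, dispersion = phi)$table$PValue
  expect_equal(ours$pvalue, theirs, tolerance = 1e-6)
})

test_that("common dispersion is recovered from simulated NB counts", {
  set.seed(8)
  g <- factor(rep(c("A", "B"), each = 5))
  phi_true <- 0.15
  cnt <- matrix(rnbinom(3000 * 10, mu = 60, size = 1 / phi_true), 3000, 10)
  phi_hat <- estimate_common_dispersion(cnt, g)
  expect_equal(phi_hat, phi_true, tolerance = 0.15)
})

test_that("null p-values of every method are uniform or super-uniform", {
  d <- null_design(n_peaks = 2000, replicates = 3)
  m <- simulate_counts(d)
  for (meth in c("wilcoxon", "ttest", "moderated_t", "nb_exact")) {
    p <- run_method(meth, m)$pvalue
    for (alpha in c(0.01, 0.05, 0.1)) {
      bound <- alpha + 3 * sqrt(alpha * (1 - alpha) / length(p))
      expect_lte(mean(p <= alpha), bound)
    }
  }
})

test_that("run_method dispatches transparently and validates externals", {
  d <- small_design(n_peaks = 300, replicates = 3)
  m <- simulate_counts(d)
  # dispatch equals a direct call
  direct <- student_t_test(logcpm_transform(m$counts), m$condition)
  via <- run_method(method_spec("ttest"), m)
  expect_equal(via$pvalue, direct$pvalue)
  # the 3v3 wilcoxon minimum raw p is 0.1
  expect_equal(min(run_method("wilcoxon", m)$pvalue), 0.1)
  # an external stub echoing p = 1 yields zero calls at any cutoff
  stub <- tempfile(fileext = ".R")
  writeLines(c(
    'a <- commandArgs(trailingOnly = TRUE)',
    'd <- read.delim(a[1])',
    'write.table(data.frame(peak_id = d$peak_id, pvalue = 1), a[3],',
    '            sep = "\\t", quote = FALSE, row.names = FALSE)'), stub)
  spec <- method_spec("external", command = paste("Rscript", stub))
  res <- run_method(spec, m)
  expect_true(all(res$padj == 1))
  # malformed output (missing peaks) is rejected
  bad <- tempfile(fileext = ".R")
  writeLines(c(
    'a <- commandArgs(trailingOnly = TRUE)',
    'd <- read.delim(a[1])[1:10, ]',
    'write.table(data.frame(peak_id = d$peak_id, pvalue = 1), a[3],',
    '            sep = "\\t", quote = FALSE, row.names = FALSE)'), bad)
  expect_error(run_method(method_spec("external",
                                      command = paste("Rscript", bad)), m),
               "missing")
})
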