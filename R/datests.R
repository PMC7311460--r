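#' Describe a differential-accessibility method
#'
#' A small container naming one of the built-in test strategies (or an
#' external command) together with its options. Built-in methods:
#' \describe{
#'   \item{wilcoxon}{two-sided rank-sum test on log2-CPM.}
#'   \item{ttest}{two-sided two-sample t-test on log2-CPM (Welch by
#'     default; \code{var_equal = TRUE} for the pooled form).}
#'   \item{moderated_t}{empirical-Bayes moderated t on log2-CPM, optionally
#'     with a batch covariate and/or mean-variance precision weights.}
#'   \item{nb_exact}{negative-binomial exact test on raw counts with a
#'     common conditional-ML dispersion.}
#'   \item{external}{a command run through a file contract (counts TSV in,
#'     p-value TSV out), letting any external tool be benchmarked.}
#' }
#'
#' @param method method name (see above).
#' @param ... options: \code{prior_count} (default 2), \code{var_equal},
#'   \code{voom_weights}, \code{batch_covariate} (logical: include the
#'   matrix's batch factor in the design), \code{dispersion_mode},
#'   \code{command} (external only).
#' @return an object of class \code{"method_spec"}.
#' @export
method_spec <- function(method = c("wilcoxon", "ttest", "moderated_t",
                                   "nb_exact", "external"), ...) {
  method <- match.arg(method)
  opts <- list(...)
  if (method == "external" && is.null(opts$command))
    stop("external methods need a 'command' option")
  structure(list(method = method, options = opts), class = "method_spec")
}

#' @export
print.method_spec <- function(x, ...) {
  cat("Method:", x$method)
  if (length(x$options))
    cat(" (", paste(names(x$options), unlist(lapply(x$options, format)),
                    sep = " = ", collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Run one differential-accessibility method on a simulated matrix
#'
#' Dispatches a [method_spec()] to its implementation. Count-space methods
#' (\code{nb_exact}) receive raw counts; the rank and t-type methods receive
#' [logcpm_transform()] output. External methods are invoked as
#' \code{command <counts.tsv> <design.tsv> <out.tsv>}; the output TSV must
#' contain columns \code{peak_id} and \code{pvalue} covering every peak, and
#' is validated before BH adjustment.
#'
#' @param spec a [method_spec()] (or a method name, for default options).
#' @param x a \code{"peak_matrix"} from [simulate_counts()], or any list with
#'   \code{counts} and \code{condition} entries.
#' @return a \code{"da_result"} data frame (see [wilcoxon_test()]).
#' @export
run_method <- function(spec, x) {
  if (is.character(spec)) spec <- method_spec(spec)
  stopifnot(inherits(spec, "method_spec"))
  counts <- x$counts
  groups <- x$condition
  opts <- spec$options
  prior <- opts$prior_count %||% 2
  batch <- if (isTRUE(opts$batch_covariate)) {
    if (is.null(x$batch)) stop("matrix carries no batch factor")
    x$batch
  } else NULL
  switch(spec$method,
    wilcoxon = wilcoxon_test(logcpm_transform(counts, prior_count = prior),
                             groups),
    ttest = student_t_test(logcpm_transform(counts, prior_count = prior),
                           groups, var_equal = isTRUE(opts$var_equal)),
    moderated_t = moderated_t_test(
      logcpm_transform(counts, prior_count = prior), groups, batch = batch,
      voom_weights = isTRUE(opts$voom_weights),
      counts = counts, prior_df = opts$prior_df),
    nb_exact = nb_exact_test(counts, groups,
                             dispersion_mode = opts$dispersion_mode %||% "common",
                             dispersion = opts$dispersion,
                             prior_count = prior),
    external = run_external_method(opts$command, counts, groups, prior))
}

run_external_method <- function(command, counts, groups, prior_count) {
  dir <- tempfile("extmethod")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  counts_f <- file.path(dir, "counts.tsv")
  design_f <- file.path(dir, "design.tsv")
  out_f <- file.path(dir, "result.tsv")
  write_count_table(counts, counts_f)
  write.table(data.frame(sample = colnames(counts), condition = groups),
              design_f, sep = "\t", quote = FALSE, row.names = FALSE)
  status <- system(paste(command, shQuote(counts_f), shQuote(design_f),
                         shQuote(out_f)))
  if (status != 0L) stop("external method exited with status ", status)
  if (!file.exists(out_f)) stop("external method produced no output file")
  out <- read.delim(out_f, stringsAsFactors = FALSE)
  if (!all(c("peak_id", "pvalue") %in% names(out)))
    stop("external output must have columns 'peak_id' and 'pvalue'")
  missing <- setdiff(rownames(counts), out$peak_id)
  if (length(missing))
    stop("external output is missing ", length(missing), " peak(s)")
  out <- out[match(rownames(counts), out$peak_id), ]
  if (any(is.na(out$pvalue) | out$pvalue < 0 | out$pvalue > 1))
    stop("external p-values malformed")
  lc <- logcpm_transform(counts, prior_count = prior_count)
  ga <- which(groups == levels(factor(groups))[1])
  gb <- which(groups == levels(factor(groups))[2])
  stat <- if ("statistic" %in% names(out)) out$statistic else rep(NA_real_, nrow(out))
  new_da_result(rownames(counts), row_fc(lc, ga, gb), stat, out$pvalue,
                "external")
}
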