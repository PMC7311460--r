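#' Confusion counts for truth-labelled calls
#'
#' Tallies true/false positives and negatives for a set of
#' differential-accessibility calls against ground-truth labels. A peak is a
#' real positive when its true mean difference is greater than zero.
#'
#' @param truth per-peak ground truth: either a numeric vector of mean
#'   differences (0 = true negative) or a logical vector (TRUE = real
#'   positive). If both arguments are named, names are used to align them
#'   and must match.
#' @param calls logical vector: was the peak called differentially
#'   accessible?
#' @return an object of class \code{"confusion"}: a list with integer
#'   components \code{tp}, \code{fp}, \code{tn}, \code{fn}.
#' @export
confusion <- function(truth, calls) {
  if (!is.null(names(truth)) && !is.null(names(calls))) {
    if (!setequal(names(truth), names(calls)))
      stop("truth and calls refer to different peak ids")
    calls <- calls[names(truth)]
  } else if (length(truth) != length(calls)) {
    stop("truth and calls must cover the same peaks")
  }
  if (anyNA(calls)) stop("calls must be TRUE/FALSE")
  pos <- if (is.logical(truth)) truth else truth > 0
  structure(list(tp = sum(pos & calls), fp = sum(!pos & calls),
                 tn = sum(!pos & !calls), fn = sum(pos & !calls)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d  (recall %s, FPR %s)\n",
              x$tp, x$fp, x$tn, x$fn,
              format(recall(x), digits = 4), format(fpr(x), digits = 4)))
  invisible(x)
}

#' False positive rate, recall, and false discovery proportion
#'
#' \code{fpr()} is FP / (FP + TN); \code{recall()} (equivalently the true
#' positive rate / sensitivity) is TP / (TP + FN), the fraction of real
#' differentially accessible regions recovered. \code{false_discovery_proportion()}
#' is FP / (TP + FP) - the fraction of calls that are false, a different
#' quantity from the FPR and reported under its own name. All three return
#' \code{NA} (missing, not zero) when their denominator is zero.
#'
#' @param x a \code{"confusion"} object.
#' @return a rate in \code{[0, 1]}, or \code{NA} if undefined.
#' @export
fpr <- function(x) {
  stopifnot(inherits(x, "confusion"))
  if (x$fp + x$tn == 0L) return(NA_real_)
  x$fp / (x$fp + x$tn)
}

#' @rdname fpr
#' @export
recall <- function(x) {
  stopifnot(inherits(x, "confusion"))
  if (x$tp + x$fn == 0L) return(NA_real_)
  x$tp / (x$tp + x$fn)
}

#' @rdname fpr
#' @export
false_discovery_proportion <- function(x) {
  stopifnot(inherits(x, "confusion"))
  if (x$tp + x$fp == 0L) return(NA_real_)
  x$fp / (x$tp + x$fp)
}

#' ROC curve and area under the curve
#'
#' Sweeps the calling threshold over every distinct p-value and records
#' (FPR, recall) at each step. Peaks with identical p-values enter as a
#' single threshold step (one diagonal segment), which makes the curve - and
#' its trapezoid area - invariant to input order. The curve is anchored at
#' (0, 0) and (1, 1). On tie-free inputs the AUC equals the normalized
#' Mann-Whitney U statistic of the p-values between the two truth classes.
#'
#' @param pvalues per-peak raw p-values.
#' @param truth per-peak truth as in [confusion()]; at least one positive
#'   and one negative peak are required.
#' @return an object of class \code{"roc_curve"}: a data frame with columns
#'   \code{fpr} and \code{recall} plus an \code{auc} attribute.
#' @export
roc_curve <- function(pvalues, truth) {
  pos <- if (is.logical(truth)) truth else truth > 0
  if (length(pvalues) != length(pos))
    stop("pvalues and truth must cover the same peaks")
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0L || nneg == 0L)
    stop("ROC needs at least one positive and one negative peak")
  ord <- order(pvalues)
  p <- pvalues[ord]; y <- pos[ord]
  last <- !duplicated(p, fromLast = TRUE)   # one step per distinct p
  tp <- cumsum(y)[last]; fp <- cumsum(!y)[last]
  pts <- data.frame(fpr = c(0, fp / nneg, 1), recall = c(0, tp / npos, 1))
  pts <- unique(pts)
  auc <- sum(diff(pts$fpr) * (head(pts$recall, -1) + tail(pts$recall, -1)) / 2)
  structure(pts, auc = auc, class = c("roc_curve", "data.frame"))
}

#' @rdname roc_curve
#' @param roc a \code{"roc_curve"} object.
#' @export
auc <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  attr(roc, "auc")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x), attr(x, "auc")))
  invisible(x)
}

#' Evaluate calls against ground truth, stratified
#'
#' Scores one method's results on one simulated matrix: recall per
#' tier-by-class stratum (classes with a real difference), FPR per tier
#' (the 0 class) and overall, at the given adjusted-p cut-off. BH adjustment
#' is genome-wide (across all peaks), matching how the tests are run.
#'
#' @param result a \code{"da_result"}.
#' @param truth the \code{truth} data frame of a \code{"peak_matrix"}.
#' @param cutoff adjusted-p cut-off for calling (default 0.05).
#' @param fpr_definition \code{"methods"} for FP/(FP+TN) (the default
#'   benchmark metric) or \code{"fdp"} for the false-discovery proportion
#'   FP/(TP+FP).
#' @return data frame with columns \code{tier_cpm}, \code{mean_diff},
#'   \code{n_peaks}, \code{recall}, \code{fpr}; class-0 rows carry the FPR,
#'   positive classes the recall, and a final row (\code{tier_cpm = NA})
#'   gives the overall rates.
#' @export
evaluate_calls <- function(result, truth, cutoff = 0.05,
                           fpr_definition = c("methods", "fdp")) {
  stopifnot(inherits(result, "da_result"))
  fpr_definition <- match.arg(fpr_definition)
  if (!setequal(result$peak_id, truth$peak_id))
    stop("result and truth refer to different peak ids")
  calls <- setNames(result$padj < cutoff, result$peak_id)[truth$peak_id]
  fpr_fun <- if (fpr_definition == "methods") fpr else false_discovery_proportion
  overall <- confusion(truth$mean_diff, calls)
  strata <- unique(truth[c("tier_cpm", "mean_diff")])
  strata <- strata[order(strata$tier_cpm, strata$mean_diff), ]
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    sel <- truth$tier_cpm == strata$tier_cpm[i] &
      truth$mean_diff == strata$mean_diff[i]
    if (strata$mean_diff[i] > 0) {
      cc <- confusion(rep(TRUE, sum(sel)), calls[sel])
      data.frame(tier_cpm = strata$tier_cpm[i], mean_diff = strata$mean_diff[i],
                 n_peaks = sum(sel), recall = recall(cc), fpr = NA_real_)
    } else {
      ## FPR within the tier's null peaks; the FDP variant needs the tier's
      ## calls among positives too, so it is computed on the tier slice.
      tsel <- truth$tier_cpm == strata$tier_cpm[i]
      cc <- confusion(truth$mean_diff[tsel], calls[tsel])
      data.frame(tier_cpm = strata$tier_cpm[i], mean_diff = 0,
                 n_peaks = sum(sel), recall = NA_real_, fpr = fpr_fun(cc))
    }
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(tier_cpm = NA_real_, mean_diff = NA_real_,
                               n_peaks = nrow(truth),
                               recall = recall(overall),
                               fpr = fpr_fun(overall)))
  out
}

#' Simulate, test, and score across a replicate/method grid
#'
#' Runs the full benchmark loop: for each of \code{n_repeats} independent
#' simulated files (each generated once with the design's full replicate
#' count and down-sampled by leading columns), each requested replicate
#' count, and each method, computes per-stratum recall and FPR at the
#' cut-off, then aggregates mean and SD over the repeats. Deterministic
#' given the design seed: repeat \code{i} uses seed \code{seed + i - 1}.
#'
#' @param design a [simulation_design()].
#' @param methods list of [method_spec()] objects (or method names).
#' @param replicate_counts replicate counts to evaluate (each at most the
#'   design's \code{replicates}).
#' @param cutoff adjusted-p cut-off (default 0.05).
#' @param n_repeats number of simulated files (default: the design's).
#' @param fpr_definition see [evaluate_calls()].
#' @return an object of class \code{"benchmark_summary"}: a list with
#'   \code{per_repeat} (stratum rows per repeat) and \code{summary}
#'   (mean/SD of recall and FPR over repeats, per stratum x method x
#'   replicate count).
#' @export
benchmark_sweep <- function(design, methods, replicate_counts = design$replicates,
                            cutoff = 0.05, n_repeats = design$n_repeats,
                            fpr_definition = "methods") {
  stopifnot(inherits(design, "sim_design"))
  if (!length(methods)) stop("no methods requested")
  methods <- lapply(methods, function(m)
    if (is.character(m)) method_spec(m) else m)
  names(methods) <- vapply(methods, `[[`, "", "method")
  if (any(replicate_counts > design$replicates))
    stop("replicate counts exceed the generated replicates")
  per <- list()
  for (i in seq_len(n_repeats)) {
    full <- simulate_counts(design, seed = design$seed + i - 1L)
    for (k in replicate_counts) {
      mat <- if (k == design$replicates) full else subset_replicates(full, k)
      for (m in names(methods)) {
        res <- run_method(methods[[m]], mat)
        ev <- evaluate_calls(res, mat$truth, cutoff, fpr_definition)
        ev$repeat_id <- i; ev$replicates <- k; ev$method <- m
        ev$depth <- design$depth
        per[[length(per) + 1L]] <- ev
      }
    }
  }
  per <- do.call(rbind, per)
  ## paste keeps the overall rows (NA stratum labels) in the aggregation
  key <- paste(per$tier_cpm, per$mean_diff, per$replicates, per$method)
  agg <- do.call(rbind, lapply(split(per, key), function(d) {
    data.frame(tier_cpm = d$tier_cpm[1], mean_diff = d$mean_diff[1],
               replicates = d$replicates[1], depth = d$depth[1],
               method = d$method[1], n_peaks = d$n_peaks[1],
               mean_recall = mean(d$recall), sd_recall = sd(d$recall),
               mean_fpr = mean(d$fpr), sd_fpr = sd(d$fpr))
  }))
  rownames(agg) <- NULL
  structure(list(per_repeat = per, summary = agg),
            class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat(sprintf("Benchmark over %d repeat(s), %d summary strata\n",
              length(unique(x$per_repeat$repeat_id)), nrow(x$summary)))
  print(head(x$summary, 12), ...)
  if (nrow(x$summary) > 12L) cat("...\n")
  invisible(x)
}
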