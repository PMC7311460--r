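#' Read a peak-count table
#'
#' TSV with a header row of sample ids; the first column holds peak ids.
#' Peak ids must be unique and, in count mode, every cell must be a
#' non-negative integer (errors name the offending row and column).
#'
#' @param path file path.
#' @param integer_mode require integral non-negative values (default TRUE).
#' @return numeric matrix with peak ids as rownames and sample ids as
#'   colnames.
#' @export
read_count_table <- function(path, integer_mode = TRUE) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 2L) stop("count table needs a peak-id column and >= 1 sample")
  ids <- as.character(d[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicated peak id: ", dup[1])
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(d[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)[1, ]
    stop("non-numeric value at row ", bad[1], ", column '",
         colnames(d)[-1][bad[2]], "'")
  }
  if (integer_mode) {
    bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
      stop("non-integer count at row ", bad[1, 1], " (peak ", ids[bad[1, 1]],
           "), column '", colnames(m)[bad[1, 2]], "'")
  }
  rownames(m) <- ids
  m
}

#' Write a peak-count (or numeric) table
#'
#' Inverse of [read_count_table()]: first column \code{peak_id}, then one
#' column per sample. Non-integer values are written with 6 significant
#' digits so that repeated runs produce byte-identical files.
#'
#' @param counts matrix with rownames (peak ids) and colnames (sample ids).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_count_table <- function(counts, path) {
  vals <- if (all(counts == round(counts))) format(counts, trim = TRUE,
                                                  scientific = FALSE)
          else format(signif(counts, 6), trim = TRUE, scientific = FALSE)
  d <- data.frame(peak_id = rownames(counts), vals, check.names = FALSE,
                  stringsAsFactors = FALSE)
  colnames(d) <- c("peak_id", colnames(counts))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample design tables
#'
#' Design tables are TSV with columns \code{sample}, \code{condition} and
#' optionally \code{batch}.
#'
#' @param path file path.
#' @return data frame with \code{sample}, \code{condition} (factor) and, if
#'   present, \code{batch} (factor).
#' @export
read_design_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(d)))
    stop("design table needs columns 'sample' and 'condition'")
  d$condition <- factor(d$condition)
  if ("batch" %in% names(d)) d$batch <- factor(d$batch)
  d
}

#' Write a simulated matrix to a directory
#'
#' Writes the three benchmark files for one simulated matrix: the count
#' table (\code{counts.tsv}), the truth table (\code{truth.tsv}: peak id,
#' tier CPM, mean difference, direction) and the design table
#' (\code{design.tsv}: sample, condition, batch).
#'
#' @param x a \code{"peak_matrix"}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default none).
#' @return invisibly, the paths written.
#' @export
write_peak_matrix <- function(x, dir, prefix = "") {
  stopifnot(inherits(x, "peak_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("counts.tsv", "truth.tsv",
                                           "design.tsv")))
  write_count_table(x$counts, paths[1])
  write.table(x$truth, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  design <- data.frame(sample = colnames(x$counts), condition = x$condition,
                       batch = if (!is.null(x$batch)) x$batch else "b1")
  write.table(design, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write a differential test result table
#'
#' TSV with columns peak id, log2 fold change, statistic, raw and adjusted
#' p-value; numbers carry 6 significant digits for byte-stable output.
#'
#' @param result a \code{"da_result"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_da_result <- function(result, path) {
  stopifnot(inherits(result, "da_result"))
  d <- data.frame(peak_id = result$peak_id,
                  log2fc = signif(result$log2fc, 6),
                  statistic = signif(result$statistic, 6),
                  pvalue = signif(result$pvalue, 6),
                  padj = signif(result$padj, 6))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive a stage seed from the global seed
#'
#' Deterministically maps (global seed, stage name) to a 31-bit seed with a
#' small polynomial string hash, so that adding a stage to a pipeline never
#' perturbs the randomness of earlier stages.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return an integer seed in \code{[0, 2^31)}.
#' @export
derive_seed <- function(seed, stage) {
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Run a configured pipeline of benchmark stages
#'
#' Executes a chain of stages described by a structured config (YAML file or
#' an equivalent nested list) and writes every artifact plus a manifest
#' (inputs, seeds, package version, and MD5 checksums of the outputs) to the
#' output directory, so any summary row can be regenerated from the manifest
#' alone. Supported stages: \code{simulate}, \code{test}, \code{evaluate},
#' \code{sweep}, \code{ruv}, \code{becorrect}. Stage seeds derive from the
#' global seed via [derive_seed()].
#'
#' @param config path to a YAML config file, or a list. Top level:
#'   \code{seed}, \code{out_dir}, \code{stages} (named list of stage
#'   parameter lists).
#' @param out_dir output directory, overriding the config.
#' @return the output directory, invisibly; artifacts and
#'   \code{manifest.yaml} are written there.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory")
  seed <- config$seed %||% 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  state <- list()
  for (stage in names(config$stages)) {
    par <- config$stages[[stage]] %||% list()
    res <- tryCatch(switch(stage,
      simulate = {
        design <- do.call(simulation_design,
                          par[intersect(names(par),
                                        names(formals(simulation_design)))])
        mat <- simulate_counts(design, seed = derive_seed(seed, "simulate"))
        if (!is.null(par$batch_effect_size)) {
          batch <- rep_len(c("b1", "b2"), ncol(mat$counts))
          mat <- batch_inject(mat, batch, par$batch_effect_size,
                              seed = derive_seed(seed, "batch"))
        }
        written <- c(written, write_peak_matrix(mat, out_dir))
        state$matrix <- mat
        NULL
      },
      test = {
        mat <- state$matrix %||% stop("no simulated matrix in scope")
        spec <- do.call(method_spec, c(list(par$method %||% "ttest"),
                                       par[setdiff(names(par), "method")]))
        state$result <- run_method(spec, mat)
        f <- file.path(out_dir, paste0("result_", spec$method, ".tsv"))
        write_da_result(state$result, f)
        written <- c(written, f)
        NULL
      },
      evaluate = {
        ev <- evaluate_calls(state$result %||% stop("no test result in scope"),
                             state$matrix$truth,
                             cutoff = par$cutoff %||% 0.05,
                             fpr_definition = par$fpr_definition %||% "methods")
        f <- file.path(out_dir, "evaluation.tsv")
        ev_out <- ev
        ev_out$recall <- signif(ev_out$recall, 6)
        ev_out$fpr <- signif(ev_out$fpr, 6)
        write.table(ev_out, f, sep = "\t", quote = FALSE, row.names = FALSE)
        written <- c(written, f)
        NULL
      },
      sweep = {
        design <- do.call(simulation_design,
                          c(par[intersect(names(par),
                                          names(formals(simulation_design)))],
                            list(seed = derive_seed(seed, "sweep"))))
        bm <- benchmark_sweep(design,
                              methods = par$methods %||% list("ttest"),
                              replicate_counts = par$replicate_counts %||%
                                design$replicates,
                              cutoff = par$cutoff %||% 0.05,
                              n_repeats = par$n_repeats %||% design$n_repeats)
        f <- file.path(out_dir, "summary.tsv")
        sm <- bm$summary
        for (cc in c("mean_recall", "sd_recall", "mean_fpr", "sd_fpr"))
          sm[[cc]] <- signif(sm[[cc]], 6)
        write.table(sm, f, sep = "\t", quote = FALSE, row.names = FALSE)
        written <- c(written, f)
        NULL
      },
      ruv = {
        counts <- if (!is.null(par$counts)) read_count_table(par$counts)
                  else state$matrix$counts
        condition <- if (!is.null(par$design)) {
          dd <- read_design_table(par$design)
          dd$condition[match(colnames(counts), dd$sample)]
        } else state$matrix$condition
        fit <- ruvr_correct(counts, condition, k = par$k %||% 3)
        f1 <- file.path(out_dir, "corrected.tsv")
        f2 <- file.path(out_dir, "W.tsv")
        write_count_table(fit$corrected_counts, f1)
        w <- fit$W
        dimnames(w) <- list(colnames(counts), paste0("W", seq_len(ncol(w))))
        write.table(data.frame(sample = rownames(w),
                               signif(w, 6), check.names = FALSE),
                    f2, sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(state$matrix)) state$matrix$counts <- fit$corrected_counts
        written <- c(written, f1, f2)
        NULL
      },
      becorrect = {
        track <- read_bedgraph(par$bedgraph %||% stop("becorrect needs a bedgraph"))
        raw <- read_peak_table(par$raw_counts)
        adj <- read_peak_table(par$adjusted_counts)
        corr <- correct_track(track, raw, adj, par$sample,
                              per_base = isTRUE(par$per_base))
        f <- file.path(out_dir, "corrected.bedgraph")
        write_bedgraph(corr, f)
        written <- c(written, f)
        NULL
      },
      stop("unknown stage '", stage, "'")),
      error = function(e) stop("stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE))
  }
  manifest <- list(package = "atacbench",
                   version = as.character(packageVersion("atacbench")),
                   seed = seed,
                   stage_seeds = lapply(setNames(nm = names(config$stages)),
                                        function(s) derive_seed(seed, s)),
                   config = config$stages,
                   outputs = as.list(setNames(unname(md5sum(written)),
                                              basename(written))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
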