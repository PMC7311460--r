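# Shared fixtures: small-scale designs and toy becorrect inputs, all built
# in code at test time.

small_design <- function(n_peaks = 3100, replicates = 3, sd_fraction = 0.10,
                         depth = 30e6, seed = 42L) {
  simulation_design(depth = depth, sd_fraction = sd_fraction,
                    replicates = replicates, seed = seed, n_peaks = n_peaks)
}

## A null-only design: every peak in the 0 class.
null_design <- function(n_peaks = 2000, replicates = 3, seed = 7L,
                        sd_fraction = 0.10) {
  simulation_design(classes = data.frame(diff = 0, prop = 1),
                    replicates = replicates, sd_fraction = sd_fraction,
                    seed = seed, n_peaks = n_peaks)
}

## Write a toy bedgraph file and return its path.
toy_bedgraph <- function(lines, header = "track type=bedGraph name=toy") {
  f <- tempfile(fileext = ".bedgraph")
  writeLines(c(header, lines), f)
  f
}

toy_peak_table <- function(start, end, counts, chrom = "chr1",
                           sample = "s1") {
  d <- data.frame(chrom = chrom, start = start, end = end,
                  peak_id = paste0("p", seq_along(start)),
                  stringsAsFactors = FALSE)
  d[[sample]] <- counts
  d
}

## Brute-force two-sided rank-sum p-value by enumerating every labeling.
enumerate_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- combn(n, n1)
  u_all <- apply(combs, 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  lo <- mean(u_all <= u_obs); hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

## Signal mass of a bedgraph restricted to [start, end) on one chromosome.
mass_in <- function(bg, chrom, start, end) {
  iv <- bg$intervals
  iv <- iv[iv$chrom == chrom & iv$end > start & iv$start < end, ]
  if (!nrow(iv)) return(0)
  sum(iv$density * (pmin(iv$end, end) - pmax(iv$start, start)))
}
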