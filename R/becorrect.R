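#' Read a bedgraph track
#'
#' Parses a 4-column UCSC bedgraph (chrom, start, end, density; 0-based
#' half-open, whitespace-delimited). Leading \code{track}/\code{browser}/\code{#}
#' header lines are kept verbatim so they can be echoed to the output
#' unchanged. Intervals are validated (numeric coordinates, start < end,
#' non-negative span) and sorted within each chromosome, with a warning if
#' the input was out of order; chromosome order follows first appearance.
#' The original density strings are retained so that untouched intervals
#' round-trip bit-identically.
#'
#' @param path file path (or connection) to a bedgraph file.
#' @return an object of class \code{"bedgraph"}: a list with \code{header}
#'   (character vector, possibly empty) and \code{intervals} (data frame
#'   with \code{chrom}, \code{start}, \code{end}, \code{density},
#'   \code{density_chr}).
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  is_header <- grepl("^(track|browser)\\b|^#", lines)
  ## header lines must be leading; anything later is a data error
  header <- lines[cumprod(is_header) == 1]
  body <- lines[seq_along(lines) > length(header)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("bedgraph has no data lines")
  fields <- strsplit(trimws(body), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop("line ", which(nf != 4L)[1] + length(header),
         ": expected 4 columns, found ", nf[nf != 4L][1])
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  dens <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(dens))
  if (length(bad))
    stop("line ", bad[1] + length(header), ": non-numeric coordinate or density")
  if (any(start >= end))
    stop("line ", which(start >= end)[1] + length(header), ": start >= end")
  iv <- data.frame(chrom = m[, 1], start = start, end = end, density = dens,
                   density_chr = m[, 4], stringsAsFactors = FALSE)
  chrom_order <- unique(iv$chrom)
  reordered <- FALSE
  parts <- lapply(chrom_order, function(ch) {
    d <- iv[iv$chrom == ch, ]
    if (is.unsorted(d$start)) {
      reordered <<- TRUE
      d <- d[order(d$start), ]
    }
    if (any(d$start[-1] < head(d$end, -1)))
      stop("overlapping intervals on ", ch)
    d
  })
  if (reordered) warning("input intervals were out of order; sorted")
  structure(list(header = header, intervals = do.call(rbind, parts)),
            class = "bedgraph")
}

#' Write a bedgraph track
#'
#' Writes header lines verbatim, then tab-separated intervals. Densities
#' whose original text is known and whose value was not changed are emitted
#' with their original string; recomputed densities use up to 6 significant
#' digits.
#'
#' @param x a \code{"bedgraph"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(inherits(x, "bedgraph"))
  iv <- x$intervals
  dens <- if ("density_chr" %in% names(iv) && !anyNA(iv$density_chr))
    iv$density_chr else format(iv$density, digits = 6, trim = TRUE,
                               scientific = FALSE)
  lines <- c(x$header,
             paste(iv$chrom, format(iv$start, scientific = FALSE, trim = TRUE),
                   format(iv$end, scientific = FALSE, trim = TRUE), dens,
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.bedgraph <- function(x, ...) {
  cat(sprintf("bedgraph: %d interval(s) on %d chromosome(s)%s\n",
              nrow(x$intervals), length(unique(x$intervals$chrom)),
              if (length(x$header)) sprintf(" (%d header line(s))",
                                            length(x$header)) else ""))
  invisible(x)
}

#' Read a peak table with per-sample counts
#'
#' Peak tables are TSV with columns \code{chrom}, \code{start}, \code{end},
#' \code{peak_id}, then one column per sample (raw or adjusted counts, or
#' CPM). Peaks must be non-overlapping within a chromosome; they are sorted
#' on read.
#'
#' @param path file path.
#' @return data frame with the coordinate columns and one numeric column per
#'   sample.
#' @export
read_peak_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "start", "end", "peak_id")
  if (!all(need %in% names(d)))
    stop("peak table needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(d$peak_id))
    stop("duplicated peak id: ", d$peak_id[duplicated(d$peak_id)][1])
  d <- d[order(d$chrom, d$start), ]
  for (ch in unique(d$chrom)) {
    s <- d[d$chrom == ch, ]
    if (nrow(s) > 1 && any(s$start[-1] < head(s$end, -1)))
      stop("overlapping peaks on ", ch)
  }
  rownames(d) <- NULL
  d
}

## Per-peak multiplicative factors adj/raw for one sample, with the
## raw == 0 fallback (factor 1 + warning).
peak_factors <- function(raw, adjusted, sample) {
  for (tab in list(raw, adjusted))
    if (!sample %in% names(tab))
      stop("sample '", sample, "' absent from the peak tables")
  if (!identical(raw$peak_id, adjusted$peak_id)) {
    if (!setequal(raw$peak_id, adjusted$peak_id))
      stop("raw and adjusted tables cover different peaks")
    adjusted <- adjusted[match(raw$peak_id, adjusted$peak_id), ]
  }
  if (!all(raw$chrom == adjusted$chrom & raw$start == adjusted$start &
           raw$end == adjusted$end))
    stop("raw and adjusted tables disagree on peak coordinates")
  cr <- raw[[sample]]; ca <- adjusted[[sample]]
  if (any(cr < 0) || any(ca < 0)) stop("negative peak counts")
  fac <- ca / cr
  zero <- cr == 0
  if (any(zero)) {
    warning(sum(zero), " peak(s) with zero raw count; factor 1 used")
    fac[zero] <- 1
  }
  data.frame(chrom = raw$chrom, start = raw$start, end = raw$end,
             peak_id = raw$peak_id, factor = fac, stringsAsFactors = FALSE)
}

#' Correction factor at genomic positions
#'
#' Evaluates the four-regime multiplicative correction at positions along
#' one chromosome, given that chromosome's sorted non-overlapping peaks and
#' their adjusted/raw count ratios:
#' \enumerate{
#'   \item before the first peak: the first peak's factor;
#'   \item after the last peak: the last peak's factor;
#'   \item inside a peak: that peak's factor;
#'   \item between two peaks (previous peak ends at \eqn{L_0}, next starts
#'     at \eqn{L_1}): linear interpolation
#'     \eqn{\frac{L_1 - L_d}{L_1 - L_0} f_0 + \frac{L_d - L_0}{L_1 - L_0} f_1}.
#' }
#' The factor function is continuous across regime boundaries.
#'
#' @param position numeric vector of positions \eqn{L_d} on the chromosome.
#' @param peaks data frame with \code{start}, \code{end}, \code{factor} for
#'   one chromosome, sorted and non-overlapping.
#' @return numeric vector of multiplicative factors.
#' @export
correction_factor <- function(position, peaks) {
  if (!NROW(peaks)) return(rep(1, length(position)))
  stopifnot(all(c("start", "end", "factor") %in% names(peaks)))
  if (is.unsorted(peaks$start)) stop("peaks must be sorted by start")
  s <- peaks$start; e <- peaks$end; f <- peaks$factor
  np <- length(s)
  out <- numeric(length(position))
  j <- findInterval(position, s)           # index of last peak starting <= pos
  before <- j == 0L
  out[before] <- f[1]
  inside <- !before & position < e[pmax(j, 1L)]
  out[inside] <- f[j[inside]]
  after_last <- !before & !inside & j == np
  out[after_last] <- f[np]
  between <- !before & !inside & !after_last
  if (any(between)) {
    jb <- j[between]
    l0 <- e[jb]; l1 <- s[jb + 1L]; pos <- position[between]
    out[between] <- (l1 - pos) / (l1 - l0) * f[jb] +
      (pos - l0) / (l1 - l0) * f[jb + 1L]
  }
  out
}

## Split one chromosome's intervals at the peak boundaries so that every
## fragment lies wholly inside one regime, then apply the factor evaluated
## at the fragment midpoint (regime 4) or the peak factor (regimes 1-3).
correct_chrom <- function(iv, peaks, per_base = FALSE) {
  if (!NROW(peaks)) return(iv)                    # no peaks: pass through
  bounds <- sort(unique(c(peaks$start, peaks$end)))
  pieces <- lapply(seq_len(nrow(iv)), function(i) {
    s <- iv$start[i]; e <- iv$end[i]
    cuts <- bounds[bounds > s & bounds < e]
    fs <- c(s, cuts); fe <- c(cuts, e)
    if (per_base) {
      ## exact per-base evaluation: one unit-width line per base
      unit_fs <- unlist(mapply(function(a, b) a:(b - 1), fs, fe,
                               SIMPLIFY = FALSE))
      fs <- unit_fs; fe <- unit_fs + 1
    }
    data.frame(chrom = iv$chrom[i], start = fs, end = fe,
               density = iv$density[i],
               density_chr = iv$density_chr[i] %||% NA_character_,
               source = i, stringsAsFactors = FALSE)
  })
  frag <- do.call(rbind, pieces)
  fac <- correction_factor((frag$start + frag$end) / 2, peaks)
  new_density <- frag$density * fac
  changed <- fac != 1
  frag$density <- new_density
  frag$density_chr[changed] <- NA_character_
  ## Re-merge adjacent fragments of the same source line whose corrected
  ## densities agree (restores the input verbatim under the identity
  ## correction, and never merges across input lines).
  keep_run <- c(TRUE, !(frag$source[-1] == head(frag$source, -1) &
                        frag$end[-nrow(frag)] == frag$start[-1] &
                        new_density[-1] == head(new_density, -1)))
  run <- cumsum(keep_run)
  merged <- frag[keep_run, ]
  merged$end <- tapply(frag$end, run, max)
  merged$source <- NULL
  merged
}

#' Adjust a bedgraph track to match corrected peak counts
#'
#' Applies the four-regime correction (see [correction_factor()]) to a
#' signal track: every interval is split at peak boundaries so each output
#' fragment lies wholly within one regime; within regime 4 the interpolated
#' factor is evaluated at the fragment midpoint (or per base with
#' \code{per_base = TRUE}). Chromosomes without peaks pass through
#' unchanged. When the raw and adjusted tables agree, the output equals the
#' input exactly. Signal mass over a peak (density times width) scales by
#' exactly the peak's adjusted/raw ratio.
#'
#' @param track a \code{"bedgraph"} (see [read_bedgraph()]).
#' @param raw,adjusted peak tables (see [read_peak_table()]) sharing peak
#'   ids and coordinates; counts for \code{correct_track}, CPM for
#'   \code{correct_from_cpm} (the two agree whenever the CPM tables are
#'   proportional to the count tables, since only ratios enter).
#' @param sample sample column to take the counts from.
#' @param per_base emit unit-width lines between peaks for exact per-base
#'   interpolation instead of fragment midpoints.
#' @return a corrected \code{"bedgraph"}.
#' @export
correct_track <- function(track, raw, adjusted, sample, per_base = FALSE) {
  stopifnot(inherits(track, "bedgraph"))
  fac <- peak_factors(raw, adjusted, sample)
  iv <- track$intervals
  if ("density_chr" %in% names(iv) == FALSE) iv$density_chr <- NA_character_
  out <- lapply(unique(iv$chrom), function(ch)
    correct_chrom(iv[iv$chrom == ch, ],
                  fac[fac$chrom == ch, , drop = FALSE], per_base))
  structure(list(header = track$header, intervals = do.call(rbind, out)),
            class = "bedgraph")
}

#' @rdname correct_track
#' @export
correct_from_cpm <- function(track, raw, adjusted, sample, per_base = FALSE) {
  correct_track(track, raw, adjusted, sample, per_base)
}
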