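test_that("bedgraph parsing validates, sorts, and preserves headers", {
  f <- toy_bedgraph("chr1\t0\t100\t2.5")
  bg <- read_bedgraph(f)
  expect_identical(bg$header, "track type=bedGraph name=toy")
  expect_equal(bg$intervals$start, 0)
  expect_equal(bg$intervals$end, 100)
  expect_equal(bg$intervals$density, 2.5)
  # header echoed to output unchanged
  out <- tempfile()
  write_bedgraph(bg, out)
  expect_identical(readLines(out), readLines(f))
  # out-of-order intervals are sorted with a warning
  f2 <- toy_bedgraph(c("chr1\t200\t300\t1", "chr1\t0\t100\t2"), header = character())
  expect_warning(bg2 <- read_bedgraph(f2), "out of order")
  expect_equal(bg2$intervals$start, c(0, 200))
  # malformed lines fail with their location
  expect_error(read_bedgraph(toy_bedgraph("chr1\t0\txx\t1")), "non-numeric")
  expect_error(read_bedgraph(toy_bedgraph("chr1\t100\t100\t1")), "start >= end")
  expect_error(read_bedgraph(toy_bedgraph("chr1\t0\t100")), "4 columns")
})

test_that("correction factors implement the four regimes continuously", {
  peaks <- data.frame(start = c(100, 300), end = c(200, 400),
                      factor = c(2, 3))
  # regime 3: inside a peak, the peak's own ratio (10 -> 20 doubles density)
  expect_equal(correction_factor(150, peaks), 2)
  expect_equal(3.0 * correction_factor(150, peaks), 6.0)
  # regimes 1 and 2: terminal peaks extend outward
  expect_equal(correction_factor(c(0, 50), peaks), c(2, 2))
  expect_equal(correction_factor(c(450, 1e6), peaks), c(3, 3))
  # regime 4: linear interpolation between flanking ratios
  between <- data.frame(start = c(0, 200), end = c(100, 300),
                        factor = c(1, 3))
  expect_equal(correction_factor(150, between), 2)   # midpoint, equal weights
  expect_equal(correction_factor(125, between), 1.5)
  # continuity at both regime boundaries
  expect_equal(correction_factor(100, between), 1)
  expect_equal(correction_factor(200, between), 3)
  expect_equal(correction_factor(199.999, between),
               correction_factor(200, between), tolerance = 1e-4)
  # no peaks: neutral factor
  expect_equal(correction_factor(5, data.frame()[0, ]), 1)
})

test_that("identity correction reproduces the input bit for bit", {
  f <- toy_bedgraph(c("chr1\t0\t120\t2.5", "chr1\t120\t300\t0.33",
                      "chr2\t10\t50\t7", "chr3\t0\t40\t1.25"))
  bg <- read_bedgraph(f)
  raw <- toy_peak_table(c(50, 200), c(150, 260), c(10, 25))
  out <- correct_track(bg, raw, raw, "s1")
  dst <- tempfile()
  write_bedgraph(out, dst)
  expect_identical(readLines(dst), readLines(f))
})

test_that("signal mass over each peak scales by exactly the count ratio", {
  f <- toy_bedgraph(c("chr1\t0\t80\t2", "chr1\t80\t160\t4",
                      "chr1\t160\t400\t1", "chr1\t400\t500\t3"))
  bg <- read_bedgraph(f)
  raw <- toy_peak_table(c(40, 300), c(120, 450), c(10, 8))
  adj <- raw; adj$s1 <- c(25, 2)
  out <- correct_track(bg, raw, adj, "s1")
  for (i in 1:2) {
    m_in <- mass_in(bg, "chr1", raw$start[i], raw$end[i])
    m_out <- mass_in(out, "chr1", raw$start[i], raw$end[i])
    expect_equal(m_out / m_in, adj$s1[i] / raw$s1[i], tolerance = 1e-9)
  }
  # output is a valid sorted, non-overlapping track with preserved coverage
  iv <- out$intervals
  expect_true(all(iv$start < iv$end))
  expect_true(all(diff(iv$start) > 0))
  expect_true(all(iv$start[-1] >= head(iv$end, -1)))
  expect_equal(sum(iv$end - iv$start), 500)
  expect_equal(min(iv$start), 0)
})

test_that("intervals straddling peak edges are split by regime", {
  f <- toy_bedgraph("chr1\t0\t300\t2", header = character())
  bg <- read_bedgraph(f)
  raw <- toy_peak_table(100, 200, 10)
  adj <- raw; adj$s1 <- 30
  out <- correct_track(bg, raw, adj, "s1")
  iv <- out$intervals
  # fragments: before (regime 1), inside (regime 3), after (regime 2);
  # before/after share the terminal factor 3 here, inside is exactly 3
  expect_equal(iv$start, 0)
  expect_equal(iv$density, 6)   # merged back: one uniform factor-3 line
  # distinct factors stay split
  raw2 <- toy_peak_table(c(0, 200), c(100, 300), c(10, 10))
  adj2 <- raw2; adj2$s1 <- c(20, 10)
  out2 <- correct_track(bg, raw2, adj2, "s1")
  iv2 <- out2$intervals
  expect_equal(iv2$start, c(0, 100, 200))
  expect_equal(iv2$density[1], 4)          # inside first peak, factor 2
  expect_equal(iv2$density[3], 2)          # inside second peak, factor 1
  expect_equal(iv2$density[2], 2 * 1.5)    # between, midpoint factor
  # per-base mode integrates the interpolation exactly
  out_pb <- correct_track(bg, raw2, adj2, "s1", per_base = TRUE)
  mass_between <- mass_in(out_pb, "chr1", 100, 200)
  # integral of 2 * (2 - x/100) over [100, 200) at unit steps, midpoints
  expected <- sum(2 * (1 + (200 - (100:199 + 0.5)) / 100))
  expect_equal(mass_between, expected, tolerance = 1e-9)
})

test_that("chromosomes without peaks pass through unchanged", {
  f <- toy_bedgraph(c("chr1\t0\t100\t2", "chrUn\t5\t25\t9.5"),
                    header = character())
  bg <- read_bedgraph(f)
  raw <- toy_peak_table(20, 80, 5)
  adj <- raw; adj$s1 <- 10
  out <- correct_track(bg, raw, adj, "s1")
  un <- out$intervals[out$intervals$chrom == "chrUn", ]
  expect_equal(un$density, 9.5)
  expect_identical(un$density_chr, "9.5")
})

test_that("CPM tables behave like count tables up to shared scaling", {
  f <- toy_bedgraph(c("chr1\t0\t400\t2"), header = character())
  bg <- read_bedgraph(f)
  raw <- toy_peak_table(c(50, 250), c(150, 350), c(10, 40))
  adj <- raw; adj$s1 <- c(30, 20)
  by_counts <- correct_track(bg, raw, adj, "s1")
  # proportional CPM tables give identical output
  raw_cpm <- raw; raw_cpm$s1 <- raw$s1 / 7.3
  adj_cpm <- adj; adj_cpm$s1 <- adj$s1 / 7.3
  by_cpm <- correct_from_cpm(bg, raw_cpm, adj_cpm, "s1")
  expect_equal(by_cpm$intervals$density, by_counts$intervals$density)
  # rescaling both tables by any common constant changes nothing
  raw_sc <- raw; raw_sc$s1 <- raw$s1 * 3
  adj_sc <- adj; adj_sc$s1 <- adj$s1 * 3
  expect_equal(correct_track(bg, raw_sc, adj_sc, "s1")$intervals$density,
               by_counts$intervals$density)
  # all-zero adjusted CPM zeroes the signal inside peaks
  adj0 <- adj; adj0$s1 <- c(0, 0)
  out0 <- correct_from_cpm(bg, raw, adj0, "s1")
  expect_equal(mass_in(out0, "chr1", 50, 150), 0)
  expect_equal(mass_in(out0, "chr1", 250, 350), 0)
})

test_that("degenerate peak tables are handled explicitly", {
  f <- toy_bedgraph("chr1\t0\t100\t2", header = character())
  bg <- read_bedgraph(f)
  # zero raw count: neutral factor with a warning
  raw <- toy_peak_table(10, 60, 0)
  adj <- raw; adj$s1 <- 5
  expect_warning(out <- correct_track(bg, raw, adj, "s1"), "zero raw count")
  expect_equal(out$intervals$density, 2)
  # unknown sample
  expect_error(correct_track(bg, raw, adj, "nope"), "absent")
  # overlapping peaks rejected on read
  tf <- tempfile()
  write.table(toy_peak_table(c(0, 50), c(100, 150), c(1, 2)), tf,
              sep = "\t", quote = FALSE, row.names = FALSE)
  d <- read.delim(tf)
  expect_error(read_peak_table(tf), "overlapping")
})
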