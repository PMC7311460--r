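---
title: "Benchmarking differential accessibility methods on simulated ATAC-seq counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking differential accessibility methods on simulated ATAC-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacbench)
```

## What the package models

Differential accessibility analysis asks, for each open chromatin region
(OCR), whether its ATAC-seq read density differs between two conditions.
`atacbench` provides a controlled laboratory for that question: a simulator
whose ground truth is known exactly, native implementations of the classical
test strategies, an evaluation layer, a residual-factor batch correction, and
a bedgraph track adjuster. This vignette records the model, the parameters
that matter, and the design decisions taken where more than one reasonable
choice existed.

## The simulator

Each simulated experiment is described by a `simulation_design()`:

* **Tier mix** — peaks are assigned a nominal density in counts per million
  of effective reads (reads under peaks). The default mix, 60% at 1 CPM, 30%
  at 5 CPM and 10% at 10 CPM, mirrors the left-skewed density distribution of
  real ATAC-seq data, where low-signal distal elements dominate. Tier (and
  class) assignment is deterministic — exact proportions, not multinomial
  sampling — so composition never fluctuates between repeats.
* **Mean-difference classes** — 80% of peaks are true negatives; 5% each
  carry a relative difference $f \in \{0.1, 0.2, 0.5, 1.0\}$. The two
  condition means preserve the tier density $c$ as their average while the
  high condition exceeds the low by the fraction $f$:
  $$\mathrm{low} = \frac{2c}{2+f}, \qquad \mathrm{high} = \mathrm{low}\,(1+f).$$
  For $c = 5$, $f = 0.5$ this gives 4 and 6 CPM. Within every tier-by-class
  cell, directions alternate so half the differential peaks are higher in
  each condition.
* **Noise** — each replicate's density is drawn from
  $\mathcal N(\mu,\ (\sigma_f\,\mu)^2)$ where $\mu$ is *that condition's*
  mean and $\sigma_f$ is the in-group SD fraction (default 0.10; 0.20 models
  a noisy experiment). The SD is anchored on the condition's own mean rather
  than the tier nominal: noise proportional to signal is the natural reading
  for density data and keeps the two conditions' coefficients of variation
  equal.
* **Depth and counts** — densities convert to integer counts as
  $\mathrm{round}(\mathrm{cpm} \times \mathrm{depth}/10^6)$ and are clamped
  at zero. Negative Gaussian draws are truncated, not redrawn: the simplest
  reproducible rule, with negligible bias at the default settings (the
  smallest mean count is $\tfrac{2}{3} \times 10 = 6.7$ at 1 CPM and 10 M
  reads, more than 4 SDs from zero at $\sigma_f = 0.1$).
* **Peak count** — the number of peaks is derived from the tier mix by
  requiring the expected total density to be $10^6$ CPM,
  $N = \mathrm{round}(10^6 / \sum_t p_t c_t)$, which makes realized library
  sizes match the nominal depth. The default mix gives $N = 322{,}581$; `n_peaks`
  can override this for scaled-down runs.
* **Replicates** — 20 per condition by default; down-sampling for replicate
  sweeps takes the *leading* columns of each condition (`subset_replicates()`),
  so a $k$-replicate analysis is a deterministic subset of the generated
  file. A seeded random subset is available but is not the default.

The generator is bit-reproducible: the same design and seed always give the
same matrix, and `batch_inject()` (a log-normal peak-specific scaling of one
batch's samples) provides a labelled fixture for the correction stage without
touching the truth labels.

## The test strategies

All rank- and t-type tests run on $\log_2$ CPM with a library-size-scaled
prior count ($p_j = p\,L_j/\bar L$, default $p = 2$), the standard transform
for count matrices; the NB exact test runs on raw counts.

* **Wilcoxon rank-sum** — exact conditional p-values (via the rank-sum null
  distribution) whenever there are no ties and $n_1+n_2 \le 25$; otherwise
  the normal approximation with tie and continuity correction. A consequence
  worth internalizing: with three replicates per group the smallest two-sided
  p-value is $2/\binom{6}{3} = 0.1$, so after any multiple-testing
  adjustment the test can never call anything in small designs.
* **Two-sample t** — the default is the Welch form (unequal variances,
  Satterthwaite degrees of freedom), the behaviour of R's `t.test()` and
  therefore of the classical interactive analysis this strategy represents;
  `var_equal = TRUE` gives the pooled form. The distinction matters:
  at three replicates the Welch denominator's effective degrees of freedom
  dip toward 2, and its heavy tails cost most of the power at genome-wide
  adjusted thresholds — which is precisely the qualitative behaviour this
  benchmark exists to expose. Zero-variance peaks with differing means
  report the smallest representable positive p-value (flagged by a warning)
  rather than 0, keeping BH and log-scale plots finite.
* **Moderated t** — per-peak linear models (condition, plus an optional
  batch covariate placed ahead of the condition effect); residual variances
  are shrunk toward a prior by empirical Bayes,
  $$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$
  with $d_0, s_0^2$ obtained by moment-matching the log residual variances
  to a scaled-F model (trigamma inversion by Newton iteration, tolerance
  $10^{-8}$, 50 iterations cap). The moderated statistic has $d_0 + d$
  degrees of freedom. `prior_df` exposes the limits: $d_0 = 0$ is exactly
  the ordinary pooled t; $d_0 = \infty$ tests every peak against the common
  variance. Optional precision weights follow the mean–variance trend idea
  (lowess of quarter-root residual SDs against mean log counts, inverted at
  per-observation fitted values); they default to off and the benchmark's
  headline results do not use them.
* **NB exact** — a common dispersion $\phi$ is estimated by maximizing the
  conditional likelihood of within-group counts given group sums (equal
  library sizes assumed; the simulator produces near-equal sizes, and
  quantile adjustment for strongly unequal libraries is deliberately out of
  scope). Under these assumptions the conditional distribution of one
  group's sum given the peak total is negative hypergeometric — free of the
  mean — so all peaks sharing a total share one null distribution, and the
  genome-wide test costs one tail computation per *distinct* total. The
  two-sided p-value is the total probability of outcomes as or less likely
  than the observed split, with the customary $(1+10^{-7})$ relative slack
  for numerically tied atoms. A numerical note: the log of the rising
  factorial $\log \binom{k+r-1}{k}$ is accumulated as
  $\sum_{i<k}\log(r+i) - \log k!$ rather than through `lgamma(k + r)`,
  which loses absolute precision once $r = n/\phi$ is large — exactly the
  dispersion-to-zero regime where the test must collapse onto the binomial
  test.
* **BH adjustment** — the step-up rule, delegated to `stats::p.adjust`
  behind input validation; all methods are compared at adjusted $p < 0.05$
  unless stated otherwise.
* **External methods** — any tool can enter the benchmark through a file
  contract (counts TSV and design TSV in, `peak_id`/`pvalue` TSV out),
  validated for completeness before adjustment. Re-implementations of the
  shrinkage-heavy NB packages are intentionally not included; the NB exact
  test is the in-package representative of that family.

## Evaluation

`confusion()` counts TP/FP/TN/FN against the truth labels (positives are
peaks with a true mean difference). Two false-positive notions coexist in
practice and are kept under separate names: the false positive rate
FP/(FP+TN) — the default metric — and the false-discovery proportion
FP/(TP+FP). Degenerate denominators yield `NA`, never silent zeros. ROC
curves sweep the raw p-values with tied values entering as single threshold
steps (making the trapezoid AUC order-invariant and equal to the normalized
Mann–Whitney statistic on tie-free input); operating points at adjusted
cut-offs use the BH values. BH is applied genome-wide — across all peaks of
a file — matching how the tests are actually run; per-tier recall is then
read off the genome-wide calls.

`benchmark_sweep()` wraps the loop: repeats $\times$ replicate counts
$\times$ methods, aggregated as mean $\pm$ SD over repeats, deterministic
given the design seed.

## Batch correction

`residual_matrix()` fits per-peak least squares of log-CPM on the condition
and returns residuals (orthogonal to the design by construction). Residuals
on log-CPM were chosen over NB deviance residuals: they are deterministic,
cheap at genome scale, and the right scale for the factor analysis that
follows; a deviance-residual mode is a clean extension point.
`ruvr_correct()` takes the first $k$ sample-side singular vectors of the
centered residual matrix as unwanted factors $W$ (sign-fixed so each
column's largest-magnitude entry is positive), regresses log-CPM on $W$
peak by peak, removes the fitted unwanted component, and writes counts back
by inverting the log-CPM transform (round, clamp at zero). The default
$k = 3$ follows common practice for removing a small number of dominant
unwanted factors; it is always user-settable, and library sizes can
optionally be taken from upper-quartile scaling instead of column sums.

One subtlety is documented rather than hidden: re-*estimating* factors on
corrected output and removing them again is not a no-op for any
residual-factor method — the second SVD simply finds the next $k$ noise
directions. Removal is idempotent in the meaningful sense: re-applying the
*same* $W$ changes nothing, because the corrected values are orthogonal to
it. The tests pin down exactly that form.

## Bedgraph adjustment

Corrected counts live in tables; browser tracks live in bedgraph intervals.
`correct_track()` maps table-level corrections onto a track with a
four-regime rule for the multiplicative factor at a position: before the
first peak and after the last, the terminal peak's $C_\mathrm{adj}/C_\mathrm{raw}$;
inside a peak, that peak's ratio; between two peaks, the linear interpolation
of the flanking ratios. Because a bedgraph line spans a range while the rule
is positional, every interval is first split at peak boundaries so each
fragment lies wholly in one regime; regime-4 fragments evaluate the factor
at their midpoint (a `per_base` mode emits unit-width lines when exact
per-base interpolation is wanted). Fragments from the same input line whose
corrected densities agree are re-merged, so an identity correction
reproduces the input byte for byte, header lines included. Zero raw counts
would make the ratio undefined; the factor falls back to 1 with a warning —
a neutral pass-through being the least surprising behaviour. Coordinates are
0-based half-open throughout; overlapping peaks are rejected (merged peak
sets are non-overlapping by construction); CPM tables are accepted in place
of count tables since only ratios enter.

## Problem sizes, runtime, and what the tests show

The shipped test-and-acceptance runs use the full default file size
(322,581 peaks) with 5 simulation repeats for the three-replicate summaries
and replicate sweeps, and 3 repeats for the high-noise six-replicate
setting; the module tests use scaled-down designs (hundreds to thousands of
peaks) where the property under test does not depend on scale. At these
sizes the whole loop — simulate, four tests, evaluate — takes well under a
minute per file on one core, which is what makes the vectorized
implementations (and the per-unique-total NB exact test) worth their
complexity.

What passing tests do and do not show: the simulator draws Gaussian
densities with fixed, known in-group variance and near-equal library sizes.
Real ATAC-seq data adds overdispersion structure, correlated peaks,
GC and fragment-length artefacts, and genuinely unequal depths — none of
which are modelled here, deliberately (counts are the simulation target, not
reads). Conclusions about the *relative* behaviour of test strategies in
this controlled regime transfer to real data only to the extent those
additional structures do not interact with the strategy differences.

Two behaviours of the defaults deserve explicit numbers. First, the
rank-sum test's discreteness means its recall is exactly zero through five
replicates per group and first becomes positive at six — a floor effect of
the exact null distribution combined with genome-wide BH, not a power
smooth. Second, in the high-noise saturation setting (six replicates, 20%
in-group SD, 100% mean difference) the Welch t-test's recall computed by
this package plateaus near 89%, not at 100%: on the log scale a 20% in-group
SD is $0.2/\ln 2 \approx 0.29$ per observation, the resulting noncentrality
at $n = 6$ per group is about 6, and exact noncentral-t power at any
genome-wide BH threshold attainable here caps short of 1. The acceptance
script reports the computed value; treating that class as fully saturated
would require either lower noise or more replicates than this design
specifies.

## Known limitations

* The NB exact test assumes (near-)equal library sizes; it is the right
  tool for this simulator's output and for lightly normalized real matrices,
  not for strongly unbalanced designs.
* TMM-style compositional normalization and quasi-likelihood F-tests are
  out of scope; library sizes are column sums (optionally upper-quartile
  scaled in the RUV stage).
* The mean–variance precision weights are a per-observation trend inversion
  refit peak by peak; they are off by default and not tuned for speed at
  genome scale.
* `batch_inject()` models a multiplicative, peak-specific batch effect —
  adequate for exercising factor recovery, simpler than real batch
  structure.
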