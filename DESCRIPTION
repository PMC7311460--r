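Package: atacbench
Title: Benchmarking Differential Accessibility Analysis for ATAC-Seq Peak Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark differential chromatin accessibility analysis
    strategies on simulated ATAC-seq peak-count data. Provides a parameterized
    simulator of peak-count matrices with tiered signal densities and labelled
    ground truth, native vectorized implementations of the standard test
    strategies (Wilcoxon rank-sum, Student's t on log2-CPM, empirical-Bayes
    moderated t, and the negative-binomial exact test with common dispersion),
    Benjamini-Hochberg correction, recall/false-positive-rate/ROC evaluation
    with replicate down-sampling sweeps, batch-effect correction of count
    matrices by residual factor analysis (RUVr-style), and adjustment of
    bedgraph signal tracks to match batch-corrected peak counts (a BeCorrect
    style four-regime rule). A command-line front-end ties the stages into
    reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    limma,
    edgeR
Config/testthat/edition: 3
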