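Package: reliefbench
Title: Benchmarking Relief-Based Feature Selection on Simulated Epistatic Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulators and evaluation machinery for studying how well
    Relief-based feature-weighting algorithms detect epistatic interactions
    in SNP-style genotype data. Generates clean full-penetrance 2- to 5-way
    XOR interaction datasets and noisy pure/strict k-locus penetrance-table
    models (GAMETES-style) with known predictive features; scores features
    with from-scratch ReliefF, MultiSURF and MultiSURF* implementations plus
    mutual-information and random-shuffle controls; and evaluates standard
    versus absolute-value score rankings with the weakest-link power
    statistic, reported as per-position power curves and heatmaps.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
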