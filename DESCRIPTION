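Package: spikeval
Title: Spike-In Benchmarking of miRNA qRT-PCR Profiling Platforms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Evaluation framework for microRNA qRT-PCR profiling panels
    probed with synthetic spike-in miRNAs of known abundance. Computes
    specificity as false-positive-rate curves over Ct detection
    thresholds with sequence-homology attribution of cross-reactive
    false positives, fold-change (delta-Ct) recovery against the spike
    design, duplicate reproducibility, and dilution-series sensitivity
    and linearity. Includes a Smith-Waterman based homology screen
    between assay target sequences and the spiked panel, and a
    parametric Ct-table simulator (log-linear amplification, Poisson
    well occupancy, mismatch-dependent cross-reaction, no-RT background
    signals) that provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
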