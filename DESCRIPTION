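Package: proteoqc
Title: Quality Control Metrics for Reference-Material Label-Free Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quality-control framework for label-free quantitative
    proteomics built around multi-sample reference materials measured in
    replicate. Implements fraction-of-total (FOT) normalization of iBAQ
    protein intensities, a PCA-based signal-to-noise ratio (SNR) that
    contrasts between-group and within-replicate distances in the first
    two principal components, reproducibility and coefficient-of-variation
    statistics stratified by protein intensity, fold-change-based
    differential-protein calls with cross-experiment reproducibility
    frequencies, longitudinal stability monitoring, and anchor-based
    absolute quantification (copies per cell) calibrated on stable-isotope
    internal standards. A ground-truthed simulator of data-dependent
    acquisition experiments (lognormal abundances, intensity-dependent
    noise and missingness, injection-order drift, time-dependent
    degradation) makes every metric testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
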