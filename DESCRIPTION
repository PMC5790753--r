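Package: ca1circuit
Title: Quantification of Hippocampal CA1 Input Connectivity from Rabies
    Tracing and Voltage-Sensitive Dye Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies input connectivity onto hippocampal CA1 pyramidal
    neurons along the proximal-distal (transverse) axis. Implements the
    connection strength index (CSI: labeled presynaptic cells per starter
    neuron) for monosynaptic rabies tracing data, gradient summaries and
    fold-ratio comparisons across injection segments, laminar
    distributions, and a normality/equal-variance-gated statistical
    comparison procedure (t-test vs Mann-Whitney U, one-way ANOVA with
    Tukey post hoc). Also provides a voltage-sensitive dye (VSD) imaging
    pipeline for photostimulation-evoked activity: per-pixel dI/I,
    baseline-SD normalization, truncated-Gaussian spatiotemporal
    smoothing, activated-pixel masking, ROI time courses and peak
    latencies. Seeded synthetic-data generators emulate both data types
    so every stage is testable without raw micrographs or movies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
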