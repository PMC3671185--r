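Package: minipsc
Title: Quantal Analysis of Miniature Postsynaptic Currents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and quantal analysis of miniature postsynaptic currents
    in voltage-clamp recordings. Provides optimally-scaled sliding-template
    event detection (Clements-Bekkers criterion), per-event kinetic measures
    (10-90% rise time, charge transfer, weighted decay), peak-scaled
    non-stationary fluctuation analysis for unitary current, channel number
    and chord conductance, tonic-current estimation from Gaussian fits of
    all-point histograms, detection of compound network events (giant
    depolarizing potentials), and the grouped statistical battery commonly
    used to compare genotypes (Kolmogorov-Smirnov on cumulative
    distributions, unpaired t, one-way ANOVA with Bonferroni post test).
    A stochastic channel-gating simulator generates voltage-clamp traces with
    known ground truth so every stage of the pipeline can be validated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
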