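Package: dmrwave
Title: Wavelet-Based Detection of Differentially Methylated Regions
Version: 0.1.0
Authors@R:
    person("dmrwave", "developers", email = "dmrwave@example.org",
           role = c("aut", "cre"))
Description: Builds per-base methylation and hydroxymethylation ratio
    signals from per-chromosome read-count tables, reduces them with a
    dyadic discrete wavelet transform (Haar by default, with biorthogonal
    spline alternatives), and calls differentially methylated regions
    between case and control groups by thresholding group-averaged
    scaling coefficients at a chosen resolution level, with post-hoc
    coverage validation. Includes a batch mode over chromosomes, a
    command-line interface, a beta-binomial simulator with planted
    regions, and truth-aware scoring of calls.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    GenomicRanges,
    jsonlite,
    optparse,
    parallel,
    rtracklayer,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
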