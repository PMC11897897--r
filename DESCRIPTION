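Package: cycliz
Title: Intrinsic DNA Cyclizability Estimation with Biotin-Tether Debiasing
Version: 0.1.0
Authors@R:
    person("cycliz", "developers", email = "cycliz@example.org", role = c("aut", "cre"))
Description: Tools for estimating intrinsic DNA cyclizability from loop-seq style
    cyclizability measurements that carry a biotin-tether bias. Implements the
    sinusoidal tether-bias model with helical-repeat phase progression, the
    closed-form intrinsic-cyclizability solver under assumed amplitude ratios,
    fractional-window moving-average smoothing of per-base cyclizability tracks,
    the six-track smoothed estimator, a full simulation benchmark of these
    estimators, and sequence/track diagnostics (dinucleotide periodicity,
    poly(dA:dT) coverage, Fourier spectra, dyad-aligned profiles) used to detect
    residual bias. Includes readers/writers for FASTA, BED, bedGraph, wiggle and
    delimited library tables, an artificial-chromosome workflow for
    reference-free libraries, a synthetic fixture generator and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
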