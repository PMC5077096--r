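Package: gcnet
Title: Granger-Causal Effective Connectivity Between Resting-State Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for group comparisons of directed (effective)
    connectivity between large-scale brain networks from resting-state fMRI
    time courses. Provides a synthetic-data generator that plants known
    directed coupling differences between two groups of stable vector
    autoregressive processes; time-series conditioning (volume dropping,
    linear detrending, nuisance regression, zero-phase band-pass filtering,
    z-normalization, motion censoring); network-of-interest definition via
    PCA reduction, group spatial independent component analysis, template
    matching and dual-regression back-reconstruction; pairwise Granger
    causality F statistics between all network pairs on temporally
    concatenated group series; permutation-based group inference with
    Benjamini-Hochberg FDR control and circular-shift within-group
    surrogates; cost-thresholded global and local graph-efficiency curves;
    and network-strength-to-behavior regressions with summary-statistic
    group tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    ica,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
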