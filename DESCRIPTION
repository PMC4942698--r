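Package: sequenceness
Title: Detection of Fast Spontaneous State-Reactivation Sequences in
    Sensor-Level MEG
Version: 0.9.0
Authors@R:
    person("Sequenceness", "Developers", email = "sequenceness@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting fast, spontaneous sequences of non-spatial
    state representations in sensor-level magnetoencephalography (MEG).
    Provides a six-state sequential decision task model with four behavioral
    choice models and BIC-based model comparison; a synthetic MEG generator
    with evoked localizer epochs, planted replay events and temporally
    autocorrelated sensor noise; minimal preprocessing (anti-aliased
    decimation and first-order IIR high-pass); per-state lasso logistic
    decoders with constrained balanced cross-validation; the lagged
    forward/reverse "sequenceness" cross-correlation statistic with
    state-identity permutation nulls and maximal-statistic thresholds; and
    group-level random-intercept inference. A single-config pipeline runs the
    full simulate-decode-detect workflow end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    lme4,
    Rcpp,
    rhdf5,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
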