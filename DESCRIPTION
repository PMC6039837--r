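Package: vnsnet
Title: MEG Network Topology Biomarkers for Vagus Nerve Stimulation Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Resting-state MEG analysis pipeline that predicts vagus nerve
    stimulation (VNS) seizure outcome from functional network topology.
    Computes phase-locking-value (PLV) connectivity in theta, alpha and beta
    bands, thresholds connectivity matrices at the cost maximizing global
    cost efficiency, and derives three global graph measures (modularity,
    transitivity, characteristic path length). Provides twin-based
    variance-components heritability estimation, two-way-ANOVA intraclass
    correlation test-retest reliability, bootstrap non-parametric group
    statistics with false-discovery-rate control, and a Gaussian naive Bayes
    three-group classifier evaluated under repeated balanced stratified
    cross-validation. A synthetic-cohort module generates phase-coupled
    multichannel time series and twin trait datasets so the full pipeline is
    testable without clinical recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
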