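Package: serodisc
Title: Serum ATR-FTIR Diagnostic Classification Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of serum attenuated total reflection
    Fourier-transform infrared (ATR-FTIR) spectral cohorts for binary
    diagnostic classification. Implements extended multiplicative signal
    correction (EMSC), fingerprint-region selection, vector normalization
    and spectral binning; partial least squares discriminant analysis
    (PLS-DA), random forest and linear support-vector machine classifiers
    behind a uniform contract with SMOTE rebalancing and patient-grouped
    cross-validated tuning; patient-grouped 70/30 repeated splits with
    nine-spectrum consensus prediction, sensitivity/specificity/accuracy
    summaries, pooled ROC analysis with constrained operating points;
    permutation-null validation and Gini importance profiling; and a
    synthetic cohort generator with the nested patient/biological/technical
    replicate structure of serum spectroscopy studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    ggplot2,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
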