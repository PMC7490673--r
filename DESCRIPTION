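Package: sensewarn
Title: Reconstruction-Based Anomaly Detection for Smartphone Passive-Sensing
    Early-Warning Signs of Psychotic Relapse
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting behavioral anomalies that precede psychotic
    relapse from smartphone passive-sensing streams. Includes a seeded
    synthetic-cohort simulator (circadian event streams, relapse calendars,
    two-type missingness), hourly feature extraction with DBSCAN
    significant-place mobility features, a two-type imputation scheme,
    stratified Monte Carlo data splitting, reconstruction models (fully
    connected autoencoder, bidirectional GRU sequence-to-sequence, local
    outlier factor baseline), Mahalanobis-distance anomaly scoring with
    per-participant threshold optimization, evaluation over Monte Carlo
    iterations, and post hoc effect-size and missingness analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
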