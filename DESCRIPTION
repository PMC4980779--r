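Package: cytoclust
Title: Two-Stage Clustering and Cohort Anomaly Detection for Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated gating of flow cytometry samples by a two-stage
    clustering procedure: the initial number of cell populations is estimated
    by counting significant kernel-density modes along the eigenvector
    projections of the data, cells are soft-clustered with Mahalanobis-distance
    fuzzy C-means, and redundant clusters are merged by Markov clustering of
    the cluster centers. The single-sample method extends to multi-subject
    cohorts: subjects are pooled and clustered once, per-subject median
    fluorescence intensity and population-percentage features are extracted,
    and subjects with anomalous marker profiles are flagged by a modified
    density-peak score combined with an iterative chi-square outlier test.
    Includes seeded synthetic-data generators, a weighted F-measure for
    clustering evaluation, FCS/CSV readers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    ggplot2,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
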