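Package: chunkdyn
Title: Temporal Dynamics of ERP Topographies: Clustering, TANOVA and
    Mass-Univariate Statistics for Multilevel Chunking Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for event-related potential (ERP) studies of
    text chunking with a 2x2(x2) within-subject design. Provides temporal
    K-means clustering of scalp topographies with a baseline-split stopping
    rule for selecting the number of clusters, topographic ANOVA (TANOVA)
    based on the cosine distance between condition topographies with a
    subject-level permutation null and cluster-based temporal correction,
    electrode-wise amplitude tests in sliding windows with false discovery
    rate control and onset extraction, and repeated-measures ANOVA with
    planned contrasts for reaction times. Includes readers for BrainVision
    recordings and a documented epochs container, a synthetic EEG and
    reaction-time generator with exported ground truth for validating every
    stage, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
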