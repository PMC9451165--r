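Package: exerwave
Title: Exercise Transcriptome Timelines, Inflammatory Signatures and
    Exerkine Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying the skeletal-muscle
    transcriptomic and inflammatory response to acute exercise, with an
    emphasis on type 2 diabetes. Implements a cross-study timeline
    meta-analysis with per-gene peak-time assignment and averaged
    transcriptional waves, an empirical-Bayes moderated differential
    expression engine with covariate and subject blocking, count
    filtering and logCPM normalization for paired two-group
    three-timepoint cohort designs with exercise-by-diagnosis interaction
    ranking, derivation of M1/M2 macrophage polarization signatures from
    multi-batch reference panels, Fisher overrepresentation and preranked
    gene set enrichment analysis, and exerkine utilities (area-under-curve
    induction scoring, Spearman gene ranking, comparative delta-delta-Ct,
    below-detection imputation, interquartile-range outlier masking).
    Every stage is exercisable on synthetic data with planted ground
    truth emitted alongside each dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    withr,
    optparse
Config/testthat/edition: 3
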