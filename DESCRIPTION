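Package: sedq
Title: Quantification of mRNP Condensation from Sedimentation Fractionation RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying transcriptome-wide mRNP condensation from
    sedimentation-fractionation RNA-seq (Sed-seq) experiments in which total,
    supernatant and pellet fractions are sequenced separately. Provides Bayesian
    estimation of per-experiment mixing ratios and per-transcript proportion in
    supernatant (pSup) under a negative-binomial conservation-of-mass model;
    length-controlled condensation and escape statistics (delta-Sed, eSed and
    the length-binned sedScore); a biophysical model of length-dependent
    sedimentation with nested-model F-testing; spike-in-normalized ribosome
    occupancy and association metrics from polysome fractions; smFISH
    colocalization scoring; and a synthetic-data generator with known ground
    truth for end-to-end validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
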