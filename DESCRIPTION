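Package: annotRR
Title: Reliability Metrics for Temporal Surgical Workflow Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing inter- and intra-rater reliability of
    temporal phase and step annotations of surgical videos. Ships a
    hierarchical laparoscopic Roux-en-Y gastric bypass (LRYGB) annotation
    ontology (12 phases, 46 steps, with facultative elements), exact
    millisecond-level interval algebra for time-weighted confusion
    matrices, accuracy, precision, recall, F1 and Cohen's kappa with
    symmetric ground-truth-swap averaging, and application-dependent
    metrics (average transitional delay, coefficient of transitional
    moments, noise level, and delta-relaxed agreement metrics). Includes a
    synthetic two-rater cohort generator with a configurable rater noise
    model (boundary jitter, label substitutions, spurious insertions,
    omissions) so every metric can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
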