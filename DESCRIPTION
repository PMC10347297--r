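Package: gcgbeat
Title: ECG-Free Heartbeat Detection in Gyrocardiography Signals by
    Template Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects individual heartbeats in gyrocardiography (GCG)
    recordings without a concurrent electrocardiogram, using normalized
    cross-correlation between a selected single-beat template and the
    band-passed angular-velocity signal, with prominence- and
    distance-constrained peak picking. Includes the ECG-referenced
    evaluation protocol: Pan-Tompkins R-peak detection, per-cycle
    classification of detections into true positives, false positives,
    false negatives and detection errors, sensitivity and positive
    predictive value, and inter-beat-interval agreement analysis
    (regression, Pearson correlation, Bland-Altman limits of agreement).
    A synthetic paired ECG+GCG generator with known ground truth makes
    the full pipeline testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
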