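Package: nirstreat
Title: Antidepressant Treatment Response Prediction from fNIRS and miRNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for predicting antidepressant treatment
    response (non-responder / partial responder / responder) in major
    depressive disorder from prefrontal functional near-infrared spectroscopy
    (fNIRS) recorded during a verbal fluency task, fused with a three-miRNA
    expression panel. Implements modified Beer-Lambert law conversion with an
    age- and wavelength-dependent differential pathlength factor, spline and
    wavelet motion correction, Butterworth band-pass filtering, channel
    quality control, time-domain activation features, orthogonal minimal
    spanning tree functional-connectivity network metrics, a reference-group
    PCA routine that discards the leading inter-subject-variability subspace,
    and seeded RBF support vector machine classification with macro-averaged
    evaluation. Includes a seeded synthetic cohort generator so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    igraph,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
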