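Package: nirsemotion
Title: Differentiating Positive Emotions from Frontal fNIRS Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for film-clip emotion studies
    recorded with multi-wavelength continuous-wave functional near-infrared
    spectroscopy (fNIRS). Converts raw tri-wavelength light intensity to
    oxy-/deoxy-hemoglobin concentration changes via the modified
    Beer-Lambert law, band-pass filters, baseline-corrects and epochs the
    signals into spatial feature vectors; analyses subjective Likert
    ratings (inter-rater reliability, repeated-measures manipulation
    checks with FDR-corrected post hocs, correlation structure, nonmetric
    multidimensional scaling and emotion-cluster scores); decodes emotion
    categories per participant with cross-validated linear support vector
    machines and permutation-derived chance levels; and maps channel-wise
    correlations between hemodynamic responses and emotion scores. A
    synthetic-data generator emulates the recordings and ratings of a
    13-participant, 37-clip frontal-montage study so that every stage is
    testable without access to raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Matrix,
    cluster,
    e1071,
    graphics,
    grDevices,
    signal,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
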