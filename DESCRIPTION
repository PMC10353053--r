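Package: cardioKit
Title: Intraventricular Pressure Gradients, Heart Rate Variability and
    Lesion Scoring for Rodent Myocardial-Infarction Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs relative intraventricular pressure fields from
    color M-mode transmitral velocity maps via the one-dimensional Euler
    equation (including Doppler de-aliasing), and derives total and
    segmental intraventricular pressure difference/gradient (IVPD/IVPG)
    profiles. Implements ECG fiducial measurement and heart rate
    variability analysis with rat-specific frequency bands, gross-lesion
    image intensity metrics, stained-cell counting and ordinal histology
    score summaries, and the accompanying statistics layer (Shapiro-Wilk
    screening, Kruskal-Wallis/Friedman omnibus tests with Dunn's post hoc,
    Spearman correlation with linear-regression R-squared, 2^-ddCt
    relative quantification, and one-way ANOVA sample-size estimation).
    A synthetic-phantom module generates every input modality with known
    ground truth for validation and end-to-end simulated studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    signal,
    pracma,
    png,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'phantom-spec.R'
    'phantoms-velocity.R'
    'phantoms-rr.R'
    'phantoms-ecg.R'
    'phantoms-image.R'
    'phantoms-cohort.R'
    'cmme.R'
    'cardiosignals.R'
    'imaging.R'
    'stats.R'
    'io.R'
    'workflow.R'
    'cardioKit-package.R'
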