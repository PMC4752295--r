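Package: hemowatch
Title: Early Warning of Hemodynamic Decompensation from Single-Lead ECG
Version: 0.1.0
Authors@R: person("Hemowatch", "Developers", role = c("aut", "cre"),
    email = "maintainers@hemowatch.example.org")
Description: An end-to-end analytical pipeline that detects developing
    hemodynamic instability (e.g. progressive central hypovolemia) from a
    single ECG lead before overt vital-sign changes. The pipeline segments
    the ECG into tumbling beat-count windows, removes baseline drift,
    delineates P-QRS-T fiducials, and extracts four feature families:
    peak morphology features (interval ratios, amplitude differences,
    ratios and interactions, spectral summaries of heart-rate variability
    and ECG-derived respiration), taut-string decomposition features of
    the R-R series, dual-tree complex wavelet features of the waveform,
    and the ten traditional time/frequency-domain HRV indices. A two-stage
    feature selection (mean-correlation redundancy removal, then
    cross-validated forward selection) feeds a nested cross-validated
    linear support vector machine that classifies compensated versus
    decompensating windows. A synthetic multi-subject cohort generator
    with known ground truth supports validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
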