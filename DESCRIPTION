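Package: synapredict
Title: Predicting Cochlear Synapse Counts from Auditory Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating non-invasive biomarkers of cochlear
    synaptopathy. Synthesizes sinusoidally and rectangularly
    amplitude-modulated (SAM/RAM) tones and tone pips, estimates envelope
    following response (EFR) magnitude by balanced bootstrap over
    alternating-polarity trials with a DFT-bin noise floor, summarizes
    auditory brainstem response (ABR) wave-1 growth and DPOAE input-output
    functions, and compares linear synapse-prediction models by repeated
    ear-grouped cross-validation and small-sample corrected AIC (AICc).
    Includes a seeded synthetic mouse-cohort generator emulating four
    experimental groups (young, acute noise, aged, aged plus noise) with
    focal versus broad synapse loss and collinear outer-hair-cell
    dysfunction, so the full analysis runs end-to-end without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    signal,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
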