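Package: sighstress
Title: Simulation and Dissection of Cardiovascular Responses to Paced Volitional Sighing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cardiovascular and autonomic responses to
    fixed-interval volitional sighing protocols. Simulates multi-channel
    physiological recordings (ECG-like, continuous arterial pressure,
    respiration) with known ground truth; extracts beat-level indices
    (R-to-R intervals, systolic pressure, pulse transit time, mean arterial
    pressure, a peak-to-peak respiratory sinus arrhythmia proxy, pulse wave
    velocity); computes Welch power spectral densities and low-/high-frequency
    band powers of heart rate and blood pressure variability; and dissects
    task and sex effects with covariate-structured linear mixed models,
    pairwise task contrasts, and case-deletion influence screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    data.table,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
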