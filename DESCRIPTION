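Package: ctpcit
Title: Complex Trial Protocol P300 Concealed Information Test Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for P300-based Concealed
    Information Tests run under the Complex Trial Protocol (CTP).
    Provides constrained stimulus-sequence generation (balanced
    secondary-item precedence, no immediate repeats), a synthetic
    epoched-EEG and behavior generator for oddball event-related
    potentials, an EEG preprocessing chain (resampling, Hamming-windowed
    sinc FIR bandpass, epoching, baseline correction, least-squares EOG
    regression, amplitude-based epoch rejection, linked-mastoid
    re-referencing), peak-to-peak P300 scoring by segment search,
    per-subject bootstrapped amplitude-difference classification, and
    group statistics (mixed ANOVA with Greenhouse-Geisser correction,
    within-subject Cohen's d, and noncentral-F power for within-between
    interactions).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
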