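Package: rgcstim
Title: Analysis of Electrically Evoked Retinal Ganglion Cell Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for multi-electrode-array recordings of retinal ganglion
    cells under light and electrical stimulation, aimed at characterising how
    degenerating retinas respond to prosthetic-style current pulses. Covers
    spike detection from raw traces (high-pass filtering, threshold crossing at
    a multiple of the noise standard deviation, PCA/k-means unit separation),
    light-response classification (ON/OFF/ON-OFF) and degeneration-severity
    calls, electrically evoked response quantification (baseline and evoked
    rates, relative response, PSTHs with confidence bounds, modulation
    classes), threshold estimation from pulse-amplitude and pulse-duration
    modulation curves, strength-duration curve fitting (rheobase, chronaxie),
    and per-phase charge and charge-density reporting with group statistics.
    Includes a synthetic-retina generator with ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    truncnorm,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
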