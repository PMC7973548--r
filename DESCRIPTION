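Package: obhfo
Title: Respiration-Coupled High-Frequency Oscillations in Laminar Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ketamine-dependent high-frequency
    oscillations (HFO, 80-130 Hz) and respiration-entrained delta rhythms in
    olfactory-bulb local field potentials recorded with laminar silicon
    probes. Provides Butterworth band filtering, Welch spectra and
    dominant-frequency extraction, Hilbert envelope/phase, 3-SD burst
    detection, intertrial phase clustering, Tort modulation-index
    comodulograms with a group resampling test, depth power and phase
    profiles, 1D kernel current-source-density (kCSD) reconstruction,
    multi-unit activity detection and MUA-HFO locking, normality-gated
    condition statistics (paired t / Wilcoxon / one-way ANOVA /
    Friedman with Nemenyi post-hoc), and a laminar forward-model synthetic
    data generator with full ground truth so every stage is verifiable
    without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
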