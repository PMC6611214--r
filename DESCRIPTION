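Package: sierp
Title: Single-Item Event-Related Potentials and Consumer Preference Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for inferring consumer preferences
    from single-item event-related potentials (SI-ERPs). Provides a synthetic
    generator for stimulus-locked EEG epochs with preference-dependent component
    amplitudes (P200/N200, late positive potential, positive slow wave) together
    with pairwise-choice and willingness-to-pay behaviour; ERP quantification
    (baseline correction, amplitude-based artifact rejection, peak-to-peak and
    window-mean component scores over scalp regions of interest); leave-one-out
    single-item versus group contrasts with Benjamini-Hochberg false discovery
    rate correction and logical discrimination criteria; repeated-measures
    ANOVA with Greenhouse-Geisser correction for group-level replication; and
    re-evaluation of a published single-item ERP summary table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    signal
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
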