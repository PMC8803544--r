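Package: respkit
Title: Respiratory Motion Artifact Filtering for Infant and Toddler
    Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and removing respiration-driven head
    motion artifact from resting-state fMRI motion traces in infant and
    toddler cohorts scanned during natural sleep. Computes framewise
    displacement (FD) from rigid-body realignment parameters, detects the
    respiratory frequency band in motion power spectra, derives
    cohort-level notch (band-stop) filter cutoffs from per-subject
    respiratory peaks, applies zero-phase band-stop filtering to motion
    parameters, censors frames by FD threshold with retention accounting,
    estimates parcellated functional connectivity with network-block
    summaries, and assesses split-half reliability across FD thresholds.
    Includes a synthetic cohort generator with known ground truth
    (narrow-band respiratory oscillation on the phase-encode axis,
    spontaneous displacement spikes, drift, and noise) so every pipeline
    stage can be validated without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
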