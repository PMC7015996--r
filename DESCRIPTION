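Package: dopplerprint
Title: Audio Fingerprinting of Doppler Ultrasound Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts compact spectral fingerprints from pulsed-wave Doppler
    ultrasound audio recordings and indexes a collection of recordings for
    similarity search. Each recording is summarized by a periodogram that is
    binned, band-limited and reduced to the ten most prominent spectral peaks;
    the peak prominences, heights, widths at half prominence and locations are
    collapsed into a five-element fingerprint. Fingerprint collections are
    indexed by principal component analysis and similar and dissimilar
    recording pairs are selected and ranked by Euclidean distance between
    scores. Includes a synthetic pulsatile carotid Doppler audio simulator with
    known ground-truth hemodynamics, time-domain hemodynamic indices (PSV, EDV,
    PI, RI) from velocity waveforms, and listener-panel validation statistics
    (per-rater agreement scores, Fleiss' kappa, one-sample t-test against
    chance). Reads and writes WAV and AIFF audio.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
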