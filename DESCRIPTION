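Package: hfosync
Title: Detection and Synchrony Analysis of High-Frequency Oscillations in
    Multi-Structure LFP Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising drug-induced high-frequency oscillations
    (HFOs, ~110-180 Hz) in multi-structure local field potential recordings from
    freely behaving rodents. Separates fractal and oscillatory spectral
    components by irregular resampling (IRASA), detects HFOs by fitting a
    Gaussian-plus-linear peak model to fractal-normalised spectra, maps
    zero-lag phase synchronisation and phase inversion between electrodes and
    structures, quantifies spike-LFP entrainment with von Mises statistics,
    tests firing-rate modulation, detects head-twitch responses from head
    accelerometer traces, and estimates spectral Granger causality between
    structures. Includes a synthetic-session generator with full ground truth
    so every stage of the pipeline can be validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    e1071,
    jsonlite,
    data.table,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
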