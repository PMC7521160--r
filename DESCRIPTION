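Package: ripplekit
Title: Sharp Wave-Ripple Detection and Coupling Analysis for NREM Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of sharp wave-ripples in two-channel intracranial
    local field potentials recorded during NREM sleep. Provides a ground-truth
    synthetic LFP generator; zero-phase filtering, gradient/high-frequency artifact
    rejection and stage-aware trial segmentation; duration-weighted Welch spectra
    with 1/f (power-law) adjustment; FWHM-parametrized complex Morlet time-frequency
    decomposition; amplitude-envelope correlation and phase-locking connectivity with
    time-shift surrogate normalization; debiased phase-amplitude coupling
    comodulograms; Hilbert-envelope dual-threshold ripple detection with matched
    surrogate event sets; cross-channel ripple co-occurrence statistics; and
    ripple-locked ERP, spectral, time-frequency power and intertrial phase clustering
    maps with multi-level cluster outlines and cluster-based permutation tests.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
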