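Package: gridwave
Title: Traveling-Wave Analysis of Low-Frequency Oscillations on Electrode Microgrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterizes traveling low-frequency oscillations
    recorded with two-dimensional electrode grids placed on neural tissue.
    Provides a ground-truth synthetic local field potential (LFP) generator
    with planted plane waves, oscillation-peak discovery from 1/f-detrended
    wavelet spectra, per-timepoint circular-linear plane-wave regression with
    electrode-shuffle permutation nulls, circular direction statistics
    (binning, smoothing, modality classification, Rayleigh and Hodges-Ajne
    tests, common-median comparison), event-locked directionality-consistency
    analysis with false-discovery-rate control, and an amplitude-topography
    direction classifier with label-shuffle significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
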