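Package: rifteeg
Title: Frequency-Tagging EEG Analysis with Intermodulation and Cluster Permutation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for rapid invisible frequency tagging
    (RIFT) EEG experiments. Generates synthetic multi-channel EEG epochs containing
    steady-state responses at two tagging frequencies, a condition-dependent
    nonlinear interaction producing intermodulation components (f2 - f1, f2 + f1),
    1/f background noise and an alpha oscillation. Provides minimal preprocessing
    (zero-phase band-pass and notch filtering, mastoid re-referencing,
    neighbor-weighted channel interpolation), boxcar-tapered Fourier power spectra
    with the percentage-power-change statistic, a two-tailed nonparametric
    cluster-based permutation test over a scalp adjacency graph, a per-participant
    electrode-selection procedure at the intermodulation frequency with paired
    t-test and Cohen's d, and an orchestrated end-to-end pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
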