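Package: evokesim
Title: Generative Simulation of Evoked Electrophysiological Responses and
    Temporal Generalisation Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multichannel electrophysiological (M/EEG-like) epoched
    signals from a generative model of spontaneous oscillatory dynamics with
    configurable stimulus-response mechanisms: phase resetting followed by
    frequency entrainment, additive damped oscillations, amplitude
    modulation, and an additive slow (non-oscillatory) response, all timed by
    an asymmetric piecewise-logarithmic response function with stochastic
    latency. Includes a cross-validated, time-resolved linear discriminant
    decoding read-out producing temporal generalisation matrices (TGMs),
    tools to quantify TGM features (diagonal profile, vertical slices,
    late-trial broadening, row periodicity), and a rise/fall response-shape
    sweep that fits simulated TGMs to a reference TGM by correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
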