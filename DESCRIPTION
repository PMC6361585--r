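Package: valencephys
Title: Spike-Train, Calcium-Imaging, and Place-Conditioning Analysis of
    Valence Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Event-aligned analysis of extracellular spike trains, miniscope
    calcium traces, and three-chamber place-conditioning logs for studies of
    motivational valence coding in midbrain circuits (RMTg, VTA).  Provides
    unit quality control (refractory-period and firing-rate-drift screening,
    shock-artifact blanking), peri-stimulus time histograms with baseline
    normalization at both sub-second and multi-minute timescales, per-neuron
    response-window significance classification (valence-encoding, putative
    dopamine, ramping, immediate/delayed inhibition, biphasic opponent
    responses to sustained stimuli), interspike-interval burst detection,
    population statistics (response-magnitude correlations, proportion
    contrasts, repeated-measures time-course tests with Holm-Sidak
    correction, a D'Agostino-Pearson normality gate), trial-based calcium
    response testing for projection-defined populations, and conditioned
    place preference/aversion scoring.  A synthetic-data generator with
    planted ground truth (inhomogeneous-Poisson spiking, burst clusters,
    injectable quality defects, kernel-convolved calcium transients, Markov
    chamber-transition behavior) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
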