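Package: opsignal
Title: Izhikevich Stimulus Simulation and Signal Analysis for
    Omeprazole-Proteinoid Electrochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Izhikevich spiking-neuron stimuli in five firing
    regimes (accommodation, chattering, triggered/induced, phasic, tonic),
    models the modulation of those dynamics by omeprazole-proteinoid
    complexes (added conductance, recovery attenuation, threshold and reset
    shifts, a two-pole low-pass transfer function, binding equilibrium,
    Boltzmann gating, a simplified membrane equation and a one-dimensional
    reaction-diffusion medium), and compares paired stimulus/response
    voltage traces with the descriptive, correlation, lag,
    Kolmogorov-Smirnov and error metrics used to characterise
    proteinoid recordings. Includes a ground-truth synthetic response
    generator for end-to-end validation and a command-line interface over
    CSV traces and JSON reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
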