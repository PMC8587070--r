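Package: pulsepol
Title: Classification of Suspended Particles from Densely Sampled Polarized
    Light Pulses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-particle polarimetric classification of
    suspended particles (microalgae, microplastics, sediment) from
    four-channel polarization-state-analyzer detector traces. Provides
    Stokes-Mueller algebra with instrument-matrix calibration and
    inversion, a virtual-instrument simulator that synthesizes labeled
    polarized light pulses (Lorenz-Mie spheres and parametric depolarizing
    particle models with within-pulse orientation drift), zero-phase
    low-pass filtering and threshold pulse detection, the dense-sampling
    featurization family (pulse-average through per-sample features), and
    a sigmoid backpropagation network plus SVM comparator with
    confusion-matrix evaluation and mixed-suspension count prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
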