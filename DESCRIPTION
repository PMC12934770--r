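Package: cbgtclaw
Title: Decision Dynamics of Cortico-Basal Ganglia-Thalamic Circuits Under
    Reward Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates reward learning in a reduced stochastic firing-rate
    model of the cortico-basal ganglia-thalamic (CBGT) circuit performing a
    two-choice task, and analyses how dopamine-driven corticostriatal
    plasticity reshapes within-trial decision dynamics.  Provides the CLAW
    (Circuit Logic Assessed via Walks) analysis that discretizes population
    firing rates into binary network states and functional zones, canonical
    correlation "control ensembles" linking CBGT activity to drift-diffusion
    model parameters, static Wiener first-passage-time fitting, a piecewise
    (phase-wise) drift-diffusion simulator with boundary collapse, and
    mixed-effects testing of learning effects on engagement time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
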