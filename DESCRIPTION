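Package: affsim
Title: Active Inference Simulation of Cued Sequential Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A generalized predictive-coding (generalized filtering) engine for
    inverting two-level hierarchical dynamic generative models in generalized
    coordinates of motion, coupled to action so that proprioceptive predictions
    are fulfilled by simulated motor reflexes (active inference). Ships a
    concrete model of visually cued sequential pointing movements in which
    winnerless-competition (Lotka-Volterra) attractors encode prior beliefs
    about cue sequences, and a higher level infers the context (sequential
    versus random cue order). Precision lesions on individual prediction-error
    streams simulate tonic dopamine depletion at different sites, reproducing
    set-switching failure, bradykinesia and perseveration. Includes behavioural
    metrics (reaction time, accuracy, switch latency, perseveration), lesion
    sweep experiments, deterministic synthetic fixtures, and smooth (analytic)
    noise generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
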