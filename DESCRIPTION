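Package: saccadia
Title: Parallel Cortico-Subcortical Network Models of Pro- and Antisaccade Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a cue-dependent pro-/antisaccade brightness-comparison
    task with a dual-pathway firing-rate network: a deep cortical hierarchy
    (either a small convolutional feedforward classifier or a three-layer
    Rao-Ballard predictive-coding network) running in parallel with a shallow
    subcortical pathway (a trained two-layer perceptron or a non-plastic
    recurrent excitatory-inhibitory population network). The two pathways
    converge on a pair of motor neurons whose firing rates, integrated with
    the Euler method, yield choices and reaction times via a fixed decision
    threshold. Includes stimulus generation, noise-robustness, reaction-time
    and difficulty-dependence experiments, and hierarchical image
    reconstruction from predictive-coding latents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    png
Config/testthat/edition: 3
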