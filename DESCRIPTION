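Package: asnen
Title: Neuron-Astrocyte Actor-Critic Networks for a Spatial Sequence Reward Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a biologically inspired
    neuron-astrocyte recurrent network trained as an actor-critic agent on a
    discrete spatial sequence reward task. Provides the task environment, the
    tripartite-synapse network dynamics with clipped-surrogate policy
    optimization (including vanilla RNN and LSTM baselines), event-aligned
    analysis of internal dynamics with principal components, and a fiber
    photometry pipeline (isosbestic dF/F, photobleaching correction,
    z-scoring, zero-phase filtering, slow-signal classification, epoch
    slopes, fast-transient quantification) with a synthetic two-channel
    trace generator for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    minpack.lm,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
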