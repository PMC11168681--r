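Package: gliabandit
Title: Neuron-Astrocyte Network Dynamics and Context-Dependent Bandit Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of multi-scale neuron-synapse-astrocyte
    network models. Provides the continuous-time firing-rate equations with
    Hebbian synaptic plasticity and slow astrocytic meta-plasticity, a
    two-neuron/one-astrocyte motif with fixed-point location, stability
    classification and pseudo-bifurcation analysis over the frozen astrocyte
    output, and a discrete-time trainable form of the network embedded in a
    REINFORCE policy-gradient pipeline for stationary and non-stationary
    context-cued Bernoulli bandit tasks, with recurrent-network and
    index-policy baselines (vanilla RNN, LSTM, GRU, UCB1, Thompson sampling,
    discounted and sliding-window UCB).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
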