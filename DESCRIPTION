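Package: cabot
Title: Closed-Loop Spiking Cell-Assembly Agents in a Four-Room World
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time spiking-neuron simulator and a library of neural
    abstract data types built on it: binary cell assemblies with ignition and
    persistent firing, finite-state automata whose states are cell assemblies,
    and synfire-chain timers.  On top of these it assembles a complete
    closed-loop embodied agent that lives in a four-room grid world, parses
    typed commands with a regular-grammar neural parser, extracts shape,
    colour and position percepts from a 20x20 retina, selects actions through
    timer-gated goal/fact/action assemblies, learns a spatial cognitive map of
    room-shape associations by spike-timing-dependent plasticity, and learns
    stimulus-response rules with a reward-gated Hebbian rule-selection
    network.  Episodes and batches of the explore / move-before cognitive
    mapping task can be run under regular or jittered visual input timing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
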