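Package: metaneuron
Title: Energy-Constrained Integrate-and-Fire Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of energy-constrained hybrid neuron models:
    the energy-dependent leaky integrate-and-fire (eLIF) neuron and the modified
    adaptive exponential integrate-and-fire (mAdExp) neuron, in which an explicit
    energy variable (a proxy for the ATP/ADP ratio) gates spike emission, shifts
    the leak potential, and drives ATP-sensitive potassium currents. Provides
    fixed-step integrators for single neurons under step and Poisson stimulation,
    phase-plane analysis (nullclines, fixed points with stability, saddle-node
    bifurcation currents, rebound-spiking condition), sweeps over the energetic
    health parameter modelling disease progression, classification of spiking
    behaviors (regular, adaptive, bursting, delayed, rebound, intermittent,
    depolarization block), recurrent excitatory-inhibitory network simulations
    with asynchronous-irregular activity statistics, and subthreshold feature
    extraction from current-clamp sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
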