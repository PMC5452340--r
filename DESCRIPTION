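Package: reifburst
Title: Activity-Clamp Playback and Refractory Integrate-and-Fire Burst
    Network Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how a use-dependent sodium-channel blocker can
    paradoxically increase epileptiform network bursting while suppressing
    spiking in single neurons.  Implements conductance-template construction
    from voltage-clamp current recordings (driving-force conversion with
    liquid-junction-potential correction, unitary AMPA conductance
    calibration, threshold-based template scaling), playback of excitatory
    and inhibitory conductance templates into a refractory exponential
    integrate-and-fire (rEIF) point neuron with post-spike relaxation of
    four parameters, a 100-neuron all-to-all excitatory network with
    presynaptic vesicle depletion integrated by Euler-Maruyama, spike-train
    burst metrics (latency, jitter, per-ordinal action-potential
    reliability, interburst interval statistics), and synthetic generators
    for epileptiform recordings, miniature EPSC traces and voltage traces
    with planted action potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
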