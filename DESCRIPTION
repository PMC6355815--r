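Package: lcmr
Title: Mean-Field Simulation of Laminar Cortical Column Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the collective activity of neuron groups in a sheet
    of cortical columns coupled through a thalamocortical loop, using a
    mean-field (neural mass) laminar cortex model. Neuron groups fire
    through a sigmoid rate function, communicate through delayed,
    spatially distributed synaptic connections with AMPA, NMDA and GABA
    receptor kinetics, and integrate postsynaptic potentials into a leaky
    membrane potential at 0.5 ms resolution. The package provides the
    simulation engine, band-limited noise inputs, perturbation protocols
    (synaptic gain sweeps and transients, inhibitory reversal-potential
    shifts, and scans emulating SCN1A loss-of-function mutations), and
    spectral analyses (Welch power spectral density, magnitude-squared
    coherence) used to map the excitation/inhibition phase diagram, locate
    its critical boundary, and detect hysteresis of seizure-like
    transitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    signal,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
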