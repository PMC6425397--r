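Package: dynome
Title: Connectome-Constrained Simulation of Graded-Potential Neuronal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the 'dynome' of Caenorhabditis elegans: a single-compartment
    graded-potential membrane model layered on top of gap-junction and chemical-synapse
    connectomes. Provides connectome bundle input/output with in-silico neuron ablation
    and reinsertion, a linear threshold-potential solver, block-wise adaptive ODE
    integration with live stimulus transitions, a computation/playback buffering
    protocol with seek and replay, mapping of dynamics to visual attributes for graph
    renderers, quantitative analysis of induced oscillations (periods, phases,
    responsive neurons, robustness scans), and synthetic connectome generators so that
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
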