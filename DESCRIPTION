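Package: contractnet
Title: Contraction Analysis and Stability Certificates for Plastic
    Recurrent Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates recurrent rate networks whose synapses evolve under
    correlational (inhibitory-Hebbian / excitatory-anti-Hebbian) plasticity,
    and certifies contractive stability of the combined neural-plus-synaptic
    system using logarithmic norms (matrix measures) of Jacobians.  Provides
    closed-form log norms for the induced 1- and 2-norms, metric
    transformations, stability certificates based on plasticity hypotheses,
    synaptic sparsity bounds, symmetric-part eigenvalue tests and
    excitatory-inhibitory balance, fixed-step deterministic and stochastic
    integrators for the combined dynamics, trajectory-distance diagnostics,
    seeded network fixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
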