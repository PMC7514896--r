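Package: hippoflow
Title: Hippocampal DG-CA3-CA1 Microcircuit Simulation with Synaptic
    Deletion and Information-Flow Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a 21-cell compartmental microcircuit of the
    hippocampal trisynaptic pathway (dentate gyrus, CA3, CA1) driven by
    theta-nested entorhinal and septal inputs, with AMPA/NMDA/GABA-A
    receptor kinetics and an online long-term potentiation rule.  Models
    Alzheimer's-like degeneration as staged deletion of entorhinal (EC2)
    synapses and analyses the consequences with burst statistics,
    delay-embedding complexity measures (auto mutual information, false
    nearest neighbours, correlation dimension, recurrence-plot Shannon
    entropy, maximal Lyapunov exponent) and directed information flow
    (mutual information and transfer entropy on binned spike activity).
    Ships synthetic benchmark generators (logistic and Henon maps, Lorenz
    system, coupled binary processes, theta-nested Poisson trains) with
    known properties for estimator validation, and a pipeline that runs
    the full control-versus-deletion study design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
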