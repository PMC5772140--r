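Package: netsir
Title: Non-Markovian SIR Epidemics on Configuration-Model Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic mean-field models and stochastically exact
    simulators for SIR epidemics spreading on configuration-model contact
    networks when the transmission delay and the infectious period follow
    arbitrary independent distributions. Implements the message-passing
    Volterra integral model, an age-structured edge-based compartmental
    model solved by the method of characteristics, a hierarchy of
    pairwise-like models (general configuration-model, degree-regular,
    Markovian and fixed-infectious-period variants), final-size and
    epidemic-threshold analytics based on the transmissibility, and
    event-driven and rejection-sampling network simulators with ensemble
    averaging. Cross-model equivalence of the message-passing and
    edge-based formulations is exposed as a numerical diagnostic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
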