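Package: cmcgame
Title: Stochastic Evolutionary Game Dynamics of County Medical Community
    Construction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Evolutionary game models of county medical community (CMC)
    construction: a two-subject game between the lead hospital of a CMC and
    primary healthcare institutions, and a tripartite extension adding
    government departments. Provides pure-strategy payoff matrices, expected
    payoffs, replicator dynamics with printed and payoff-derived drift
    variants, deterministic fixed-step Euler integration, stochastic
    simulation of the Ito systems with multiplicative Gaussian white noise
    via the forward Euler (Euler-Maruyama) scheme, vertex equilibrium
    stability classification, seeded ensembles, declarative parameter-sweep
    scenarios with convergence classification, flat-file configuration, CSV
    trajectory export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
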