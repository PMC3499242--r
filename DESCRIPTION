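Package: mutualsim
Title: Coevolution of Reciprocal Investments in Two-Guild Mutualisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the continuous iterated
    investment game between two mutualist guilds. Each individual carries two
    heritable traits, an unconditional initial offer and a conditional reward
    rate, and plays a linear reactive strategy over a fixed number of rounds
    against a partner from the other guild. The package provides the iterated
    game with saturating benefits and linear costs, numerical best-response
    analysis and best-response dynamics, adaptive-dynamics selection gradients
    with phase angles along the investment cycle, a stochastic individual-based
    model on paired square lattices or well-mixed pools (best-takes-over or
    Fermi pairwise-comparison updating, constant-sigma or constant-CV
    mutation, synchronous or asynchronous scheduling), and spatial diagnostics:
    bubble detection, interface replacement-dynamics classification, and
    two-bubble invasion experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
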