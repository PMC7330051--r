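Package: twitchr
Title: Agent-Based Simulation of Pili-Driven Bacterial Twitching Motility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained Langevin-dynamics simulation of twitching-mode
    bacilliform bacteria moving over a surface by a stochastic cycle of rest,
    type-IV pilus extension and pilus retraction, together with the
    statistical toolkit used to characterise their individual and collective
    dynamics: mean squared displacement and scaling exponents, non-Gaussian
    parameter, van Hove displacement distributions, directional
    auto-correlations along trajectories, pair correlations of motion and
    orientation, local-coverage coexistence distributions and number
    fluctuation scaling. Twitchers are stiff four-bead chains with WCA
    excluded volume, FENE bonds and harmonic angle rigidity in a periodic
    two-dimensional box; the engine is written in C++ for speed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
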