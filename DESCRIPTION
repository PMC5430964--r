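Package: traphop
Title: Trap-Hop Dynamics of Polymers in Slit-Confined Micropost Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study macromolecular transport in weakly attractive
    micropost arrays confined in nanoslits. Provides a coarse-grained
    Langevin dynamics simulator for a Gaussian FENE bead-spring chain among
    cylindrical posts on a hexagonal lattice, trajectory statistics for
    single-molecule center-of-mass tracks (mean squared displacement,
    short- and long-time diffusivities, displacement distributions and
    their exponential, stretched-exponential and shifted-Gaussian fits), a
    hidden-Markov "trap-hop" decoder that infers per-frame trapping
    probabilities and apparent free-energy barriers from displacement
    trajectories by Viterbi iteration, the analytic
    conformational-fluctuation barrier model, potential-of-mean-force maps
    from center-of-mass histograms, and generators of synthetic trap-hop
    and Brownian trajectories for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
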