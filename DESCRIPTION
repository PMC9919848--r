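Package: dfret
Title: Diffusion-Enhanced FRET Analysis of Flexible Chains
Version: 0.1.0
Authors@R: person("dfret", "developers", role = c("aut", "cre"),
    email = "dfret@example.org")
Description: Tools for diffusion-enhanced Foerster resonance energy transfer
    (DFRET) on flexible peptides and polymers. Solves the Haas-Steinberg
    reaction-diffusion equation for the excited-donor population of a chain
    with an r^-6 transfer sink, computes static and dynamic closed-form
    limits of the effective donor-acceptor distance, calibrates the
    diffusion-influence sigmoid over a grid of Foerster radii and contact
    distances, evaluates the resulting closed analytical surrogate, and
    globally fits end-to-end distance distributions and intramolecular
    diffusion coefficients to multi-condition effective-distance data. A
    Brownian-dynamics Monte Carlo estimator and a synthetic-experiment
    generator are included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
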