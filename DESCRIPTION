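Package: dissockit
Title: Dissociation Analysis of Protein Dimer Interfaces from Biased
    Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis stack for the dissociation of two-chain protein
    complexes sampled by metadynamics along a centre-of-mass distance
    collective variable. Computes per-frame interface descriptors
    (centre-of-mass distance, fraction of native contacts, solvent
    accessible surface area), defines bound/encounter/unbound states by
    fitted sigmoid membership functions, reconstructs free-energy
    profiles from deposited hills with time-dependent-bias reweighting
    and leave-one-out errors, types noncovalent inter-chain contacts and
    aggregates their occurrence, measures interdomain orientation
    (centre-axis distance, torsion and tilt angles), and estimates
    Markov state models (tICA, k-means microstates, PCCA+ macrostates,
    Chapman-Kolmogorov validation). A synthetic-data module provides toy
    dimers, programmed dissociation trajectories and one-dimensional
    Langevin metadynamics on known potentials so that every stage is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
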