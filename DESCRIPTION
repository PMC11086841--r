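Package: stringfes
Title: Enhanced-Sampling Free-Energy Methods for Conformational Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale implementations of the enhanced-sampling machinery used
    to map conformational transitions of molecular motors: collective-variable
    geometry (Kabsch superposition, delta-RMSD, principal-axes projections,
    distances, dihedrals, contacts), extended adaptive biasing force (eABF)
    sampling with the CZAR gradient estimator and gradient integration, the
    swarms-of-trajectories string method with equal-arc-length
    reparametrization, umbrella sampling along a path with Umbrella Integration
    and MBAR reweighting, and trajectory post-processing (hierarchical
    clustering on pairwise RMSD, representative and typical structures,
    metastable-state assignment). Estimators are exercised on analytically
    tractable model potentials with Langevin dynamics and on toy helix
    conformer ensembles, with brute-force quadrature oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
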