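Package: hdnnp
Title: Fourth-Generation High-Dimensional Neural Network Potentials with
    Charge Equilibration
Version: 0.1.0
Authors@R:
    person("hdnnp", "developers", email = "hdnnp@example.org",
           role = c("aut", "cre"))
Description: Machine-learned interatomic potentials of the
    high-dimensional neural network family, including a
    fourth-generation variant in which environment-dependent atomic
    electronegativities feed a constrained charge-equilibration solve
    with Gaussian-charge electrostatics, and the equilibrated charges
    re-enter the short-range atomic networks.  Provides atom-centered
    symmetry function descriptors with analytic gradients, cluster and
    Ewald electrostatics, analytic forces via implicit differentiation
    of the charge-equilibration system, two-stage training against
    reference charges, energies and forces, gradient-descent geometry
    optimization, a synthetic reference-data generator emulating
    non-local charge-transfer benchmark scenarios, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
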