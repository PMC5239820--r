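Package: funmetad
Title: Funnel Metadynamics Binding Free Energies on Toy Langevin Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Well-tempered funnel metadynamics analysis for host-guest
    binding free energies: funnel and wall restraint potentials, a water
    coordination-number restraint that removes trapped-solvent hysteresis,
    reconstruction of the two-dimensional free-energy surface from deposited
    Gaussian hills and its Boltzmann projection to a one-dimensional
    potential of mean force, standard-state binding free energies, a
    one-step free-energy-perturbation correction for the water restraint
    with statistical-inefficiency filtering and bootstrap errors,
    block-average convergence diagnostics, and the SAMPL error metrics
    (MAD, MADTr, AvErr, R squared). A bundled Langevin toy engine generates
    hills and collective-variable files that exercise the whole pipeline,
    including the trapped-solvent phenomenon, without an external molecular
    dynamics package.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
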