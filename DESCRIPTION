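Package: nuccg
Title: Bottom-Up Coarse-Grained Potentials for Nucleosome-Nucleosome
    Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Workflow for deriving coarse-grained nucleosome interaction
    potentials from umbrella-sampling data: construction of umbrella window
    schedules and harmonic bias restraints, generation of synthetic biased
    reaction-coordinate trajectories on reference free-energy landscapes,
    estimation of potentials of mean force by the weighted histogram
    analysis method (WHAM) with Monte Carlo bootstrap uncertainties and
    window-overlap diagnostics, least-squares fitting of harmonic,
    exponential and shifted-Coulomb coarse-grained potential forms, and
    Langevin dynamics of a covalently closed nucleosome-bead ring fiber
    driven by the fitted potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    bio3d,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
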