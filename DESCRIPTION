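Package: surfhop
Title: Trajectory Surface Hopping with Internal Conversion and Intersystem Crossing on Vibronic Coupling Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Semiclassical excited-state molecular dynamics for molecules where
    internal conversion and intersystem crossing compete. Provides a linear
    vibronic coupling (LVC) electronic-structure model over coupled singlet and
    triplet spin components (including a uracil-like default parameterization),
    harmonic Wigner sampling of initial conditions, absorption-spectrum
    simulation and delta-pulse selection of initial excited states, a
    fewest-switches surface-hopping propagator working in the fully diagonal
    spin-mixed electronic basis with energy-based decoherence, ensemble
    population analysis in diagonal, spin-free (MCH) and spectroscopic
    representations, hop statistics and geometry descriptors, and mono- and
    biexponential fitting of population kinetics with asymptotic standard
    errors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    yaml,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
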