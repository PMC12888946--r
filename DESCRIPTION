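Package: littsim
Title: Desk-Scale Simulation and Automated Control of MR-Guided Laser
    Interstitial Thermal Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulator for magnetic-resonance-guided laser interstitial
    thermal therapy (MRgLITT) of brain tumors. Solves the Pennes bioheat
    equation with temperature-dependent thermal properties on axisymmetric or
    3-D voxel phantoms, accumulates Arrhenius thermal damage with
    damage-dependent perfusion and optical attenuation, and drives the laser
    either from recorded clinical-style laser logs or from a cascaded
    PID / fuzzy-logic controller that regulates the tumor-boundary temperature
    and automatically retracts the probe in 5 mm increments on damage
    feedback. Includes closed-form solver verification, virtual MR-thermometry
    probe voxels, lesion-coverage metrics, and Sobol variance-based
    uncertainty quantification of optical parameters with a polynomial
    surrogate.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    lhs,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
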