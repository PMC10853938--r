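Package: gbsolv
Title: Solvation Free Energies from Generalized-Born Descriptors and a
    Dense Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts standard-state solvation free energies of molecules
    and ions from Cartesian geometry and total charge alone.  Atomic
    partial charges are obtained by electronegativity equalization with
    element- and coordination-number-dependent parameters; generalized-Born
    self and pair energies, spherical-cap estimates of atomic van der Waals
    surface areas and volumes, and three bulk solvent descriptors form a
    physical feature vector that is reduced by principal component analysis
    and regressed by a small dense neural network with rectified-linear
    hidden layers.  Includes the full training harness (Nadam optimizer,
    weighted squared-error loss, L2 regularization), ionic data
    augmentation across dielectric constants and boiling points, and a
    synthetic-molecule generator so every stage is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
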