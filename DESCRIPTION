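Package: hbdipole
Title: Hydrogen-Bond Energetics and Dielectrics from O-H Stretching
    Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Treats a hydrogen bond as an elastic O-H dipole sitting in the
    local electric field of its acceptor.  From a measured O-H stretching
    wavenumber the package computes the harmonic force constant, the local
    field, the stretched bond length, the bond and molecular dipole moments,
    the hydrogen-bond energy and the bond polarizability, with first-order
    (delta-method) or Monte-Carlo uncertainty propagation.  Includes the two
    calibration fits behind the model coefficients (a global shared-slope fit
    of force constant against field, and a York errors-in-variables straight
    line of bond length against field-to-force-constant ratio), a curated
    table of reference water systems (ices, gypsum, solid hydrates), a
    synthetic field-sweep generator for recovery tests, and dielectric
    predictors for nanoconfined water, layered crystals and bulk liquid water
    (Langevin-Debye with a Kirkwood correlation factor).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
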