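Package: quinrelease
Title: Kinetics of Acid-Promoted Self-Immolative Quinone Release
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Kinetic analysis machinery for acid-promoted, self-immolative
    1,6-elimination release of protected ortho-quinones from
    para-aminobenzyl ketol prodrugs. Provides microspecies protonation
    networks with pH-dependent mole fractions computed in log space,
    Eyring transition-state-theory conversion between activation free
    energies and intrinsic first-order rate constants, a global
    pH-dependent observed-rate model with multi-start weighted
    least-squares fitting of equilibrium constants to pH-rate profiles,
    first-order and sequential (Bateman) release kinetics with half-life
    estimation from spectroscopic and chromatographic time courses,
    closed-form plate and bioanalytical assay metrics, and seeded
    synthetic-data generators for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
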