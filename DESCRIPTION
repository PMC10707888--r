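Package: saptfit
Title: Atom-Pairwise Intermolecular Force Fields Fit to SAPT Component Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physics-based atom-pairwise model of intermolecular non-bonded
    interactions decomposed into the four SAPT components: damped multipole
    electrostatics, density-overlap exchange-repulsion, Tang-Toennies damped
    C6/C8/C10 dispersion, and Thole induced-dipole induction with a
    short-range overlap term. Per-atom-species global parameters are fitted
    by BFGS against reference SAPT component energies with a multi-target
    loss, trained on homodimers and evaluated on heterodimers. Includes XYZ
    input, covalent-radius bond perception and atom typing over a 17-species
    vocabulary, MAE/RMSE/MAX error reports, and a seeded synthetic-dimer
    generator for end-to-end parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
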