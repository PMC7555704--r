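Package: pyrxs
Title: Electron Scattering Cross Sections and Track Simulation for Pyridine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A complete, self-consistent integral cross-section data set for
    electron scattering by pyridine between 0.1 and 100 eV, packaged as a
    queryable library with per-channel interpolation, together with the
    semi-empirical angular and energy-loss sampling models and an
    event-by-event Monte Carlo electron transport simulator for a gas cell,
    including the magnetically confined transmission (retarding potential
    analyzer) virtual experiment used to validate the data set.  Also
    provides the dataset-construction tools (missing-angle corrections,
    closure rules) and a fitting routine for the exponent of the
    semi-empirical inelastic angular distribution, with a synthetic
    double-differential cross-section generator for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
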