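Package: mpaspec
Title: Ensemble Multiphoton Absorption Spectra and Chromophore Structure
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assembles one-, two- and three-photon absorption spectra from
    per-snapshot excited-state ensembles with Lorentzian broadening and
    Goeppert-Mayer unit conversion, analyses snapshot decorrelation via
    autocorrelation and exponential decay fits, computes retinal-chromophore
    structural descriptors (bond-length alternation, dihedral planarity) from
    multi-frame XYZ trajectories, correlates structure with excitation
    energies, and provides toy-scale electrostatic-coupling (single-center
    multipole, ESP-fitted charges, hybrid cutoff schemes) and self-consistent
    induced-dipole polarizable-embedding solvers. Includes synthetic-data
    generators with ground-truth sidecars for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
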