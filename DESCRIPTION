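Package: ndfo
Title: Electron-Balance Analysis and Kinetic Simulation of Nitrate-Dependent Fe(II) Oxidation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Stoichiometric electron-balance accounting for anoxic
    nitrate-dependent Fe(II) oxidation (NDFO) incubations: an exact-rational
    reaction network for the coupled biotic denitrification and abiotic
    chemodenitrification chemistry with element, charge and electron
    conservation checks; partitioning of consumed nitrate between nitrite
    accumulation and full reduction to dinitrogen with the corresponding
    theoretical Fe(II) demand (2 and 5 electron equivalents per mole of
    nitrate) and first-order uncertainty propagation from replicate standard
    deviations; a mass-action ODE simulator of the reaction network with a
    measurement layer (acid-extraction artifact, replicate Gaussian noise)
    that generates synthetic assay time series; and tidy assay CSV input and
    output plus qPCR standard-curve utilities for the accompanying growth
    check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
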