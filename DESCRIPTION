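Package: gpbuildup
Title: Gamma-Ray Energy-Absorption Buildup Factors of Multi-Element
    Materials by the Geometric-Progression Fitting Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes point-isotropic-source energy-absorption buildup
    factors of compounds and mixtures such as human organs and tissues.
    Implements the equivalent-atomic-number (Zeq) method: the
    Compton-to-total attenuation ratio of the material is matched against
    pure elements, geometric-progression (GP) fitting parameters are
    interpolated from an elemental library in the style of
    ANSI/ANS-6.4.3-1991, and the five-parameter GP formula of Harima and
    co-workers is evaluated on an energy grid for penetration depths up
    to 40 mean free paths.  Also provides photoelectric/Compton/pair
    crossover energies, peak-energy characterisation, effective atomic
    numbers (Zeff) by the cross-section-ratio method, tissue-equivalence
    band screening, synthetic element datasets with exact analytic
    oracles for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
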