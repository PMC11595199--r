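Package: placperm
Title: Placental Permeability Modeling with QSAR, ARKA and q-RASAR
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modeling human placental transfer of small molecules
    on the log FM scale (the base-10 logarithm of the fetal-to-maternal
    blood concentration ratio at equilibrium). Provides a bank of fixed
    published-coefficient linear models (MLR, ARKA and q-RASAR families),
    the model-building machinery behind them (ordinary least squares,
    forward stepwise selection, NIPALS partial least squares with iterative
    VIP-based variable reduction, best-subset search), kernel-similarity
    Read-Across prediction with RASAR descriptor computation and fusion,
    ARKA supervised dimensionality reduction with confidence-quadrant
    analysis, internal and external validation statistics, drug-likeness
    rule filters with cluster comparison against permeability classes, a
    seeded synthetic descriptor-table generator, and an end-to-end
    screening pipeline over delimited descriptor tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
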