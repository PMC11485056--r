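Package: gegnn
Title: Thermodynamically Consistent Graph Neural Networks for Binary
    Activity Coefficients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts composition-dependent activity coefficients of binary
    liquid mixtures from molecular graphs. A graph neural network maps two
    SMILES-encoded molecules and a mole fraction to the dimensionless molar
    excess Gibbs free energy gE/RT; activity coefficients are then obtained
    through the exact thermodynamic differential relations ln gamma1 =
    gE/RT + x2 d(gE/RT)/dx1 and ln gamma2 = gE/RT - x1 d(gE/RT)/dx1,
    evaluated by automatic differentiation of the network, so every
    prediction satisfies the Gibbs-Duhem equation by construction. Includes
    soft-constrained (Gibbs-Duhem regularised) and unconstrained direct
    predictors as baselines, composition-interpolation / extrapolation /
    unseen-mixture split protocols, a synthetic data generator built on
    classical excess-Gibbs models (two-parameter Margules, van Laar, NRTL),
    consistency and accuracy metrics, and isothermal vapor-liquid
    equilibrium construction via modified Raoult's law and the Antoine
    equation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    patchwork,
    pracma,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
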