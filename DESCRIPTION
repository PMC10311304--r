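Package: dosebayes
Title: Bayesian Dose-Response Modelling and Drug-Combination Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Hill-equation dose-response models to monotherapy vectors
    and two-drug combination matrices by Markov chain Monte Carlo, returning
    full posterior uncertainty for potency (IC50, the association parameter
    alpha) and efficacy (Einf, delta-HSA). Decouples synergistic potency,
    P(alpha > 1), from synergistic efficacy, P(delta-HSA > 0), per posterior
    draw. Includes posterior-predictive prediction of held-out responses,
    leave-out splitting protocols for 6x6 and 15-point screening layouts,
    RMSE and Monte-Carlo test-likelihood metrics, probability-integral-
    transform calibration with Kolmogorov-Smirnov uniformity testing, and a
    seeded generator of synthetic dose-response matrices from the model's
    own prior for parameter-recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
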