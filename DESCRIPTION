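Package: complementr
Title: Reduced-Order Kinetic Modeling of Human Complement Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, ensemble parameter estimation, and perturbation analysis
    for a reduced-order kinetic model of the human complement cascade (lectin and
    alternative pathways). The model couples ordinary differential equations with
    rule-based control terms (Hill transfer functions combined by min/max
    integration rules) to describe C3 and C5 convertase formation and the release
    of the C3a and C5a inflammatory fragments under varying initiator (zymosan)
    doses. Includes a hybrid particle-swarm/dynamically-dimensioned-search warm
    start, a multiobjective simulated-annealing Pareto ensemble generator,
    AIC scoring against random-parameter controls, Sobol total-order sensitivity
    analysis with Saltelli sampling, pairwise perturbation-displacement
    clustering, knockdown robustness coefficients, and a synthetic measurement
    generator emulating immunoassay time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    lhs,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
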