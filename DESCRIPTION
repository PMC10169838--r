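Package: ternarybinding
Title: Mass-Action Modelling of Adaptor-Antibody Ternary Complex Formation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Kinetic and equilibrium modelling of three-body binding between
    engineered T cells bearing universal adaptor receptors, tag-conjugated
    antibody adaptors, and antigen-positive target cells. Provides a stiff
    mass-action ODE simulator for the six-species binding network, an
    independent steady-state solver, equilibrium dose-response curves with
    hook (prozone) effect metrics, bounded least-squares fitting of kinetic
    rate constants to observed activation readouts, one-dimensional
    parameter scans, a seeded synthetic dose-response data generator, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
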