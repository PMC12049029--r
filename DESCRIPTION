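Package: betaborrow
Title: Bayesian Power-Prior Borrowing for Sequential Platform Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design and analysis tools for phase II platform trials with a
    binary endpoint that share control-arm data across sequential treatment
    rounds through fixed power priors. Provides conjugate Beta-Binomial
    posterior analysis with weighted borrowing of historical control data,
    the posterior tail probability that the treatment-arm response rate
    exceeds the control rate by a clinically meaningful margin, frequentist
    operating characteristics of the posterior decision rule by Monte-Carlo
    simulation and by exact enumeration over the discrete outcome grid,
    effective-sample-size accounting, borrowing-weight sensitivity
    reanalysis, control-drift reporting for data monitoring committees,
    synthetic patient-level data generation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
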