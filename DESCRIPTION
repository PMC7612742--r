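Package: upfsim
Title: Agent-Based Simulation of Ultra-Processed Food Purchasing Policies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based simulator of weekly household ultra-processed food
    (UPF) purchasing among adult female food purchasers, with homophilous
    small-world social networks, social-signal and social-norm adjustment
    dynamics, and policy operators for UPF taxes (via own-price elasticity),
    front-of-package nutrition warning labels (education-stratified effects)
    and advertising changes (via advertising elasticity). Includes calibration
    of free parameters to an equilibrium purchasing target, a replicated
    scenario runner with paired-seed counterfactual comparisons, and
    equity-gap reporting stratified by income and education.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
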