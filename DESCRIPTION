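Package: ssesim
Title: Agent-Based Simulation of Safety Production in Small-Scale Enterprises
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Discrete-time agent-based model of occupational safety in
    small-scale enterprises (SSEs). Profit-seeking firms choose a safety
    investment under bounded-rational self-learning while employees, the
    public, and a government regulator react: employees perceive the
    workplace safety level with cognitive bias and may expose unsafe
    conditions to the public, blow the whistle to the regulator, quit, or
    demand a raise; public reputation feeds back into sales; the regulator
    operates a banded reward-penalty transfer and tax schedule keyed to the
    evaluated safety level. The package simulates five employee-behaviour
    scenarios over seeded Monte Carlo ensembles, summarises class-count and
    profit trajectories as tibbles, ranks scenarios on a five-level ordinal
    impact scale, and compares the ranking against stored survey reference
    constants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
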