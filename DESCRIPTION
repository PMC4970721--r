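Package: lynchcea
Title: Cost-Effectiveness Modelling of Genetic Screening Strategies for Lynch Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic modelling of universal tumour-based genetic
    screening for Lynch syndrome among newly diagnosed colorectal cancer
    patients, with cascade testing of first-degree relatives. Implements
    cohort simulation, screening decision trees (IHC with and without BRAF
    reflex testing, MSI, and direct germline sequencing), a Markov
    natural-history model of colorectal cancer in mutation carriers with
    and without colonoscopic surveillance, incremental cost-effectiveness
    ratios with WHO willingness-to-pay categories, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves, and
    one-way (tornado) sensitivity analysis. Parameterised for the Taiwan
    setting by default; every input is configurable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
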