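Package: flowseg
Title: On-Line Flow-Cytometric Monitoring of Microbial Population Segregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated, on-line flow cytometry of microbial cultures
    in bioreactors: reading and writing list-mode event data (minimal FCS 3.x
    and instrument CSV exports), rectangular gating of propidium-iodide uptake
    subpopulations (healthy/intermediate/damaged), gating-free segregation
    statistics (mean-to-median ratio, degree of segregation), a mechanistic
    simulator of batch/chemostat cultures carrying a destabilized
    growth-rate-responsive GFP reporter, and a model of the automated
    sampling/dilution/staining interface between bioreactor and cytometer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
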