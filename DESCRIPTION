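Package: quorosc
Title: Coupled Quorum-Sensing Gene Oscillators: Delay Simulation,
    Hopf Maps and Synchronization Robustness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates colonies of quorum-sensing coupled synthetic gene
    oscillators of the Danino type, with or without an optogenetically
    gated negative-feedback channel on the AiiA node, using a
    method-of-steps delay differential equation integrator with dense
    output.  Classifies oscillatory versus steady-state behaviour over
    two-parameter grids, localises Hopf boundaries by bisection, computes
    synchronization metrics (absolute synchronization error, its time
    integral, and exponential-envelope synchronization rates) and runs
    paired robustness comparisons with bootstrap confidence intervals and
    Cohen's d effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
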