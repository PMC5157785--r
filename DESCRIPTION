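Package: satox
Title: Semi-Attributable Toxicity Designs for Dual-Agent Phase I Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian dose-escalation designs for dual-agent phase I trials in
    which the two drugs are administered non-concurrently within a treatment
    cycle. Models the dose-toxicity surface with a Farlie-Gumbel-Morgenstern
    copula over skeleton probabilities and distinguishes dose-limiting
    toxicities occurring before the second drug is given (attributable to the
    first drug) from those occurring afterwards (non-attributable), via a
    trinary-outcome likelihood. Provides posterior sampling by adaptive
    random-walk Metropolis with a deterministic quadrature cross-check,
    neighbourhood-constrained dose-escalation decision rules with early
    stopping, a full trial simulator with packaged true-toxicity scenarios,
    operating-characteristic summaries, broom-style tidiers, ggplot2 plotting
    methods, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
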