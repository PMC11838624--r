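Package: binsurv
Title: Cost-Optimal Surveillance and Intervention for Binary Hidden Markov Systems
Version: 0.1.0
Authors@R:
    person("binsurv", "maintainers", email = "maintainers@binsurv.org",
           role = c("aut", "cre"))
Description: Tools for designing surveillance-and-intervention protocols for a
    system whose hidden state alternates between normal and abnormal as a
    two-state Markov chain, observed through a noisy binary detector. Computes
    exact steady-state expected cost per unit time for any intervention
    strategy over length-n observation windows, derives the optimal decision
    table by thresholding the per-history Delta statistic, selects the best
    protocol across surveillance depths, classifies cost-parameter phase
    diagrams, and provides a seeded stochastic simulator that serves as an
    empirical oracle for every closed-form loss. Includes a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
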