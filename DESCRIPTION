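Package: ccesim
Title: Agent-Based Simulation of Cumulative Cultural Evolution with
    Algorithmic Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates cumulative cultural evolution in populations of
    budget-limited agents embedded in social networks. Agents acquire
    functionally dependent cultural traits (branch x complexity level,
    each carrying an integer payoff) through innovation, payoff-biased
    social learning from network neighbours, or recommendations from a
    global archive of all traits innovated so far (algorithmic
    mediation, dispatched with a tunable probability). The package
    provides the open-ended cultural trait space with lazily sampled
    payoffs, standard network generators (complete, Erdos-Renyi,
    Watts-Strogatz small-world, Barabasi-Albert scale-free, or
    user-supplied edge lists), a fast compiled simulation engine with a
    pure-R reference engine, quasi-stationary summaries of population
    performance, diversity and complexity, reproducible parameter
    sweeps, and a small command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
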