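Package: symsieve
Title: Vertical Symbiont Transmission Models and the Symbiont Sieve
Version: 1.0.0
Authors@R:
    person("Symsieve", "Developers", email = "symsieve@example.org",
           role = c("aut", "cre"))
Description: Models of how the mode of parent-to-offspring (vertical)
    transmission of microbial symbionts filters which symbionts can invade a
    host population. Uniparental (maternal) transmission acts as a sieve that
    blocks symbionts deleterious to host fitness, whereas biparental
    transmission gives rare symbionts a twofold reproductive boost and lets
    harmful ones spread. The package provides a discrete-generation frequency
    recursion for hosts carrying an augmented symbiont community together with
    its analytic invasion threshold, an individual-based continuous-time
    stochastic birth-death simulator (exact Gillespie algorithm) with sex
    structure, logistic density dependence, multi-taxon carriage, horizontal
    uptake and Y-linked transmission-modifier alleles, the matching
    deterministic two-type and six-type differential-equation systems with
    boundary equilibria, invasion rates and extinction thresholds, outcome
    classification over (fitness, horizontal-uptake) parameter grids, and a
    reproduction harness with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    truncnorm
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
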