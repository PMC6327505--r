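Package: chemevol
Title: Chemostat Competition Models for Laboratory Evolution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing prolonged chemostat cultivation and
    laboratory-evolution experiments in glucose-limited continuous culture.
    Implements deterministic Monod chemostat dynamics for competing strains,
    mutant wash-in kinetics with a closed-form logistic approximation,
    nonlinear least-squares fitting of allele-fraction time series with
    Fisher-information-based structural-identifiability diagnostics,
    cross-dilution-rate competition predictions, physiology side computations
    (specific fluxes, fermentation stoichiometry and ATP yield, mutation-rate
    estimation, Michaelis-Menten uptake kinetics, codon annotation),
    degenerate-consensus scanning of catabolite-responsive elements (cre
    sites) with position frequency matrices, and seeded synthetic-data
    generators that emulate every measurement the analysis consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
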