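Package: sitsim
Title: Population-Suppression Modeling and Fitness Statistics for Genetic
    Biocontrol of Mosquitoes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stage-structured, genotype-explicit daily-time-step population
    dynamics for comparing sterile-insect-style suppression programs (pgSIT,
    RIDL, female-specific RIDL, and Wolbachia-based IIT) released into an
    Aedes aegypti-like population, with density-dependent larval competition,
    one-mating female structure, equilibrium calibration, and deterministic
    and stochastic modes.  Also provides the two bespoke statistics behind
    sterile-male fitness claims: the Fried mate-competition competitiveness
    index with bootstrap uncertainty, and Turnbull nonparametric maximum
    likelihood estimation of survival curves from interval-censored longevity
    data with bootstrap medians and a permutation two-group comparison.
    Synthetic-data generators emulate the competition-assay and
    interval-censored survival designs so every analysis stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
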