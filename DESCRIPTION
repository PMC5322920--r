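Package: lifetabtox
Title: Life-Table Endpoints, Euler-Lotka Demography and Factorial ANOVA for
    Host-Parasite Toxicity Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for chronic (21-day) Daphnia life-history
    experiments that cross toxicant exposure with parasite challenge in a
    factorial design. Provides tidy individual-level record I/O with
    validation, per-individual endpoints (age at first reproduction, day-14
    fecundity, day-21 reproductive output) and per-treatment mortality and
    infection proportions, estimation of the per-capita intrinsic rate of
    population increase from the Euler-Lotka equation with jackknife
    pseudo-values for replication, per-clone two-way analysis of variance
    with Dunn-Sidak adjusted significance levels, and a stochastic
    individual-based simulator of the factorial designs for testing and
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
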