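Package: troposcale
Title: Scaled Nitrogen-Isotope Discrimination Framework for Trophic
    Position Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates trophic position (TP) from bulk nitrogen stable
    isotopes under a scaled diet-tissue discrimination framework.  Fits a
    Bayesian hierarchical measurement-error meta-regression of the
    discrimination factor (Delta15N) on dietary delta15N across controlled
    feeding experiments, derives the resulting saturating enrichment curve
    (asymptote delta15N_lim and per-trophic-step rate k), and inverts it to
    estimate continuous trophic positions with full posterior uncertainty.
    Also provides the conventional additive (constant 3.4 per-mil)
    estimator, discrete trophic-level grids, food-web comparison summaries,
    and seeded synthetic-data generators for controlled-feeding tables and
    food webs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    jsonlite,
    readr,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    rjags,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
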