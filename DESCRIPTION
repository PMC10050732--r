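Package: mrsuite
Title: Two-Sample Mendelian Randomization with Correlated Instruments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics, built around the analysis of genetically proxied plasma
    cortisol and periodontitis risk. Provides reading, validation and allele
    harmonization of summary statistics; instrument selection by P-value
    threshold with greedy linkage-disequilibrium clumping; instrument-strength
    F statistics and variance explained; Wald ratios; fixed-effect
    inverse-variance-weighted estimation for correlated instruments via
    generalized least squares, and classic independent-instrument IVW with
    fixed or multiplicative random effects; MR-Egger regression with its
    intercept test for directional pleiotropy; Cochran's Q and I-squared
    heterogeneity diagnostics; leave-one-out analysis; a profile-score (RAPS)
    estimator accounting for exposure-side sampling error; a priori power and
    minimum-detectable odds-ratio calculations for binary outcomes; and a
    synthetic two-cohort GWAS generator (correlated genotypes via a Gaussian
    copula, liability-threshold binary outcome, optional pleiotropy) so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
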