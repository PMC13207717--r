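Package: lipidmr
Title: Summary-Data Mendelian Randomization and Colocalization for Lipidomic Exposures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking an omics exposure panel (blood lipid species) to a
    disease outcome with two-sample summary-data Mendelian randomization using
    correlated instruments (GSMR-style generalized least squares with HEIDI
    outlier filtering), sensitivity estimators (fixed-effect IVW, MR-Egger),
    Bayesian colocalization via approximate Bayes factors with region
    construction, merging and credible sets, LD clumping against a reference
    panel, lipid nomenclature parsing and class enrichment, differential lipid
    abundance with a within-batch permutation overlap test, and cohort-level
    lipid-symptom association with polygenic scoring. Includes synthetic-data
    generators with known ground truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
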