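Package: mrtri
Title: Triangulation of Genetic Liability and the Circulating Metabolome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for triangulating evidence on the relationship between
    genetic liability to disease and circulating metabolites. Implements
    weighted genetic risk score (GRS) construction with greedy LD clumping
    and gene-region exclusions, a metabolome-wide association scan using
    robust-standard-error linear regression with per-doubling-of-liability
    scaling and false discovery rate control, two-sample Mendelian
    randomization estimators (random-effects inverse-variance weighted,
    weighted median, and weighted mode) with allele harmonization and
    instrument-strength diagnostics, and a directional-consistency
    classifier that combines the three evidence streams. A synthetic-data
    module generates genotype panels, longitudinal cohorts, and paired
    two-sample summary statistics with configurable horizontal pleiotropy,
    so that every stage of the pipeline is testable without access to
    restricted cohort or consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    sandwich,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
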