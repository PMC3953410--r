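Package: grsobesity
Title: Genetic Risk Scores for Obesity Traits and Their Modification by
    Physical Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of unweighted genetic risk scores (GRS) from
    BMI-associated SNP dosages, per-SNP quality control (call rate and the
    exact Hardy-Weinberg equilibrium test), association testing of scores
    and single variants with quantitative adiposity traits (raw and
    inverse-normal transformed) and with weight-status categories under
    Chinese BMI cut-offs, explained-variance and cross-ancestry
    heterogeneity (Cochran's Q) calculations, directional-consistency
    binomial sign tests, and GRS-by-physical-activity interaction models
    with stratified effects and attenuation. Includes a synthetic-cohort
    generator that draws Hardy-Weinberg genotypes at specified allele
    frequencies and traits under an additive model with optional
    score-by-activity interaction, so the full pipeline is testable
    without access to individual-level cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
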