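Package: sodiumGxE
Title: Genome-Wide Polymorphism x Sodium Interaction Analysis of Blood Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-wide gene-environment interaction
    scans of blood pressure against daily sodium consumption: phenotype
    preparation (blood-pressure averaging and medication imputation,
    spot-urine estimation of daily sodium excretion), variant quality
    control with an exact Hardy-Weinberg test, interaction testing under
    dosage, additive, dominant and recessive genotype codings with a
    1-df likelihood-ratio test and genomic-control correction, two-stage
    discovery/replication/combined significance evaluation, Monte-Carlo
    power calculation for the interaction test, and stratified post-hoc
    analyses (genotype-subgroup sodium slopes, sodium-tertile tables,
    hypertension odds ratios, sensitivity re-runs). Includes a synthetic
    cohort generator so the full pipeline is testable without restricted
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
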