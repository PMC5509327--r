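Package: genemeta
Title: Meta-Analysis of Genetic Association Studies from Summary Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for meta-analysing SNP-trait association studies from
    study-level summary tables: genetic-model odds ratios computed from
    genotype counts or from Hardy-Weinberg-reconstructed counts, standardized
    mean differences and per-allele regression coefficients for quantitative
    traits, inverse-variance fixed-effect and DerSimonian-Laird random-effects
    pooling with Q, I-squared, H-squared and tau-squared heterogeneity
    statistics, Egger and Begg publication-bias tests with funnel-plot data
    export, leave-one-out sensitivity analysis, population attributable risk
    under the multiplicative genotype model, and closed-form power for
    case-control and quantitative per-allele trend tests. Ships transcribed
    study tables for the G6PC2 fasting-glucose / type-2-diabetes literature
    and a synthetic multi-study data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
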