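Package: mr2s
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Complete two-sample Mendelian randomization workflow operating on
    GWAS summary statistics: harmonization of exposure and outcome association
    tables (allele orientation, strand complements, palindromic-variant policy),
    LD-based instrument pruning and proxy-variant substitution, causal
    estimation by Wald ratio, inverse-variance weighting (fixed and
    multiplicative random effects), MR-Egger regression, the weighted-median
    and mode-based estimators, Cochran's Q heterogeneity with per-variant
    outlier flagging, leave-one-out sensitivity analysis, forest/funnel plot
    tables, instrument-strength (variance explained, F statistic) and
    binary-outcome power calculations, and a seeded synthetic-data generator
    with known causal truth for estimator validation. Ships the published
    18-SNP serum-urate instrument panel with multiple sclerosis outcome
    associations as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), yaml, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
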