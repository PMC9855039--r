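Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) workflow for
    GWAS summary statistics: instrument selection (genome-wide significance,
    greedy LD clumping, confounder screening, F-statistic filtering), proxy
    substitution and allele harmonization, causal estimation by Wald ratio,
    fixed- and random-effect inverse-variance weighting, MR-Egger with
    bootstrapped standard errors, weighted median and likelihood-based MR,
    pleiotropy and influence diagnostics (Egger intercept test, MR-PRESSO,
    leave-one-out, scatter/forest/funnel tables), cross-database fixed and
    random (DerSimonian-Laird) meta-analysis with Cochran's Q and I-squared,
    statistical power for binary outcomes, and a synthetic two-cohort GWAS
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
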