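Package: mrlink
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for bidirectional two-sample Mendelian
    randomization between microbiome-abundance GWAS and protein-level
    (pQTL) GWAS summary statistics. Provides instrument selection under
    named threshold profiles (p-value filtering, greedy LD clumping
    against a reference panel, allele-frequency supplementation,
    confounder screening, pQTL annotation filtering, F-statistic and
    variance-explained metrics), allele harmonization with palindromic
    SNP handling, five causal-effect estimators (Wald ratio, fixed- and
    random-effects inverse-variance weighting, MR-Egger, weighted median,
    weighted mode), heterogeneity and pleiotropy diagnostics (Cochran's Q,
    radial per-variant contributions, a simulation-based residual
    outlier/distortion test, leave-one-out), Benjamini-Hochberg
    correction, and analytic power calculations. A synthetic GWAS
    generator with known ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
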