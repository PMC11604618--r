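Package: mrmediate
Title: Two-Sample Mendelian Randomization with Mediation Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: reading and harmonizing per-SNP association tables,
    instrument selection (p-value thresholding, greedy LD clumping,
    F-statistic filtering), causal-effect estimation (Wald ratio,
    inverse-variance-weighted, MR-Egger, weighted median, mode-based and
    multivariable IVW estimators), sensitivity diagnostics (Cochran's Q,
    Egger intercept test, MR-PRESSO outlier detection, leave-one-out),
    batch bidirectional screening with tiered Bonferroni significance,
    and two-step mediation analysis with product-of-coefficients effect
    decomposition. Includes a summary-statistics simulator with known
    ground truth for calibration and testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
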