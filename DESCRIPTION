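Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Two-sample Mendelian randomization (MR) on GWAS summary
    statistics, including instrument selection (genome-wide significance,
    greedy LD clumping, F-statistic validation), exposure-outcome
    harmonization with palindromic-SNP resolution, eight causal estimators
    (random-effects IVW, MR-Egger, simple/weighted/penalized-weighted
    median, simple/weighted mode, maximum likelihood), sensitivity
    diagnostics (Cochran's Q, Egger intercept, leave-one-out, reverse
    direction), and two-step mediation MR with the product-of-coefficients
    delta method. Ships a summary-statistic simulator for a three-trait
    exposure-mediator-outcome causal chain so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
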