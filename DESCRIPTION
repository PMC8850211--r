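Package: perimqc
Title: Response-Quality Control for Static Automated Perimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the quality of observer responses during static
    automated perimetry with the method of constant stimuli. Builds randomized
    stimulus schedules with enriched false-positive and false-negative catch
    trials, simulates observer sessions with a latent vigilance process,
    converts session records into per-second response-time, response-time
    variability (60-s sliding-window variance) and catch-trial error-rate
    series, and implements the pooled ROC/AUROC analysis with Youden-index
    cut-off selection, per-subject agreement indices on binary deviance masks,
    and per-subject Spearman rank correlation analyses with cohort-level
    meta-correlations.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    utils,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
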