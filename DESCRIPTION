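Package: adheremon
Title: Adherence Monitoring from Pill-Box Telemetry, Self-Report and Viral Load
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving antiretroviral-therapy adherence from electronic
    pill-box event streams and 30-day self-report recall, dichotomizing viral
    load, and analysing how the measures relate: chance-corrected agreement
    (Cohen's kappa and Gwet's AC1, which is robust to the "kappa paradox"
    under skewed marginals), diagnostic accuracy of poor adherence as a test
    for viral non-suppression (sensitivity, specificity, ROC/AUC with
    clinic-level cluster-bootstrap confidence intervals), and three-level
    logistic regression of monthly adherence trends with population-averaged
    (marginal) predicted probabilities. A synthetic cohort generator emulates
    a 39-clinic, twelve-month cluster-randomized adolescent ART cohort so the
    full pipeline is testable without access to trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lme4,
    lubridate,
    pROC,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
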