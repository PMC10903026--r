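Package: parage
Title: Parental Attained Age and Midlife Mortality and Hospitalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how parental attained age, used as a proxy
    for biological age in the offspring, predicts all-cause mortality and
    first-time hospitalization during midlife in a single-year birth
    cohort.  Includes a two-generation synthetic registry-cohort generator
    with gamma-frailty Gompertz-Makeham parental lifespans, a cohort
    builder implementing the exclusion cascade, exposure construction and
    ICD chapter mapping, self-contained survival machinery (Nelson-Aalen
    cumulative hazards, stratified Cox regression with the Efron tie
    correction, the k-sample log-rank test), a recursive truncated
    log-rank procedure locating the onset of risk differences between
    exposure quartiles, and a stratified counterfactual resampling
    estimator of avoidable deaths and hospitalizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
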