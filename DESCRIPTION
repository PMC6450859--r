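Package: clampkin
Title: Tracer Kinetics for Two-Stage Hyperinsulinaemic-Euglycaemic Clamps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-stage hyperinsulinaemic-euglycaemic
    clamp studies with stable-isotope glucose and glycerol tracers.
    Implements Steele's single-pool non-steady-state turnover equations
    (with the labelled-infusate modification), optimal-segments smoothing of
    concentration and enrichment time courses, tissue-specific insulin
    sensitivity indices (M, M/I, percentage suppression of endogenous
    glucose production and lipolysis, percentage stimulation of glucose
    disposal, trapezium AUCs), and the two-group comparison statistics used
    in clamp studies (Shapiro-Wilk routing, pooled-t mean differences,
    geometric-mean ratios, Mann-Whitney, Pearson correlation, covariate
    adjustment and interaction tests). A clamp simulator with known truth
    generates synthetic subjects and cohorts so every stage is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
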