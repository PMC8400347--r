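Package: bevclass
Title: Sweetened Beverage Classification and Misclassification Sensitivity
    Analysis for 24-Hour Dietary Recall Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for classifying sweetened beverages in 24-hour dietary
    recall data keyed to 8-digit foodcodes. Implements four published
    strategies for identifying low-calorie sweetened beverages (foodcode
    prefix organization, survey food categories, caloric-density criteria,
    and description text search) together with an ingredient-based
    classifier that detects "mixed" foodcodes covering branded products
    that disagree on low-calorie sweetener content. Converts recall items
    to beverage volumes with foodcode-specific density factors, assigns
    participants to consumer groups, fits design-based weighted linear
    models with Taylor-linearization variance for stratified cluster
    samples, reports least-squares means with Tukey-Kramer adjusted
    pairwise comparisons, and quantifies how the treatment of mixed
    foodcodes changes group sizes and outcome estimates via a two-scenario
    sensitivity analysis. Includes a synthetic data generator emulating
    the structure of national dietary surveillance data so that every
    pipeline stage is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
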