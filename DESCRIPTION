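Package: dsipredict
Title: Disease State Index Prediction of Global Cognitive Decline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Disease State Index (DSI), a missing-data-tolerant
    supervised classifier that combines per-feature empirical fitness functions
    by relevance-weighted averaging through a feature hierarchy, together with
    the full evaluation protocol used to assess prediction of significant
    global cognitive decline in a population cohort: construction of a general
    cognitive factor (g-factor) by principal component analysis of five
    cognitive tests, annualized delta-g outcome labelling by a 5% tail rule,
    repeated stratified 2-fold cross-validation with corrected resampled
    t-test confidence intervals, age-correction model variants,
    relevance-threshold feature selection on MRI features, and extreme-DSI
    subgroup analysis. A calibrated synthetic cohort generator emulates the
    age structure, age-driven cognitive decline, age-loaded biomarkers and
    missingness of the study population so the complete pipeline can be
    exercised and validated without access to the original cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
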