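Package: compadhere
Title: Composite Treatment-Adherence Outcomes for Multibehavior Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Outcome construction and analysis for randomized trials that
    target several treatment behaviors at once, modelled on multibehavior
    adherence trials in type 2 diabetes.  Scores physical-activity (SQUASH
    MET-minutes), snack food-frequency (weekly kilocalories) and
    medication-adherence (ProMAS sum) questionnaires; builds per-behavior
    standardized change scores and a composite standardized change score
    interpretable on the Cohen-d scale; estimates intervention effects with
    nurse-nested linear mixed models (Satterthwaite degrees of freedom);
    analyses selective attrition by logistic regression; performs multiple
    imputation by chained equations with Rubin-rule pooling and
    optimistic/pessimistic scenario-based sensitivity imputation; and
    provides design-effect sample-size and simulation-based power
    calculations.  A calibrated synthetic cohort generator reproduces the
    data structure such trials assume (nurse clustering, individual
    randomization, differential dropout) so the whole pipeline is testable
    without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    nnet,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
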