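Package: dietrbm
Title: Conditional Restricted Boltzmann Machines for Diabetes Screening and
    Diet-Exercise Recommendation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage clinical decision-support toolkit. Stage one screens
    patients for diabetes from seven-feature pathology reports using standard
    ensemble classifiers with explicit probability averaging over base
    learners. Stage two predicts food preferences for screened-positive
    patients with a conditional restricted Boltzmann machine whose hidden
    layer is conditioned on per-item similarity and popularity scores,
    trained per user group by contrastive divergence with shared sub-weight
    matrices, and turns the predicted ratings plus pathology-derived nutrient
    requirements into ranked diet plans and daily exercise schedules. Includes
    exact enumeration oracles for small models, Gibbs sampling, synthetic
    data generators with planted group structure, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    randomForest,
    e1071,
    xgboost,
    class,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
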