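# Stage-1 diabetes screening. The only bespoke content here is the ensemble
# probability average over base-learner votes; the learners themselves are
# the established implementations (randomForest, e1071, xgboost, class::knn).

#' Average base-learner probabilities into an ensemble probability
#'
#' `Prob = (1/n) * sum_i Prob(K_i)` over the per-learner (e.g. per-tree)
#' probabilities, with the diabetic label assigned when the mean reaches
#' 0.5 (ties classify as diabetic: a screening stage favours sensitivity).
#'
#' @param tree_probabilities numeric vector of per-learner probabilities in
#'   `[0,1]` (for a forest, one 0/1 vote per tree).
#' @return list with `probability` (the mean) and `label`
#'   (`"diabetic"`/`"non-diabetic"`).
#' @export
ensemble_probability <- function(tree_probabilities) {
  p <- as.numeric(tree_probabilities)
  if (length(p) == 0) stop("at least one base-learner probability required")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0,1]")
  m <- mean(p)
  list(probability = m, label = if (m >= 0.5) "diabetic" else "non-diabetic")
}

#' Screen a patient cohort for diabetes
#'
#' Fits the chosen classifier on a stratified training split of the labeled
#' cohort and scores every patient. For the random forest, the per-tree 0/1
#' votes are explicitly averaged through [ensemble_probability()]; the other
#' learners supply their native class probabilities.
#'
#' @param patients a `patient_report` data.frame ([validate_patients()]).
#' @param model_choice one of `"rf"`, `"svm"`, `"gboost"`, `"knn"`.
#' @param seed integer seed (controls the split and any stochastic fitting).
#' @param train_fraction fraction of the cohort used for fitting.
#' @return list with `results` (data.frame `patient_id`, `probability`,
#'   `label`, `split`), `metrics` (held-out [classification_metrics()]) and
#'   `model_choice`.
#' @export
screen_cohort <- function(patients, model_choice = c("rf", "svm", "gboost", "knn"),
                          seed = 1, train_fraction = 0.7) {
  model_choice <- match.arg(model_choice)
  patients <- validate_patients(patients)
  feats <- attr(patients, "feature_cols")
  if (anyNA(patients$label)) stop("screening requires a fully labeled cohort")
  y <- factor(patients$label, levels = c("non-diabetic", "diabetic"))
  if (nlevels(droplevels(y)) < 2)
    stop("training data contains a single class; cannot fit a screener")
  x <- as.matrix(patients[feats])

  set.seed(as.integer(seed))
  tr <- logical(nrow(patients))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    tr[sample(idx, max(1, round(train_fraction * length(idx))))] <- TRUE
  }

  prob <- switch(model_choice,
    rf = {
      fit <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                        ntree = 200)
      votes <- stats::predict(fit, x, predict.all = TRUE)$individual
      apply(votes == "diabetic", 1, function(v) ensemble_probability(v)$probability)
    },
    svm = {
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], probability = TRUE)
      attr(stats::predict(fit, x, probability = TRUE),
           "probabilities")[, "diabetic"]
    },
    gboost = {
      dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE],
                                  label = as.integer(y[tr]) - 1L,
                                  nthread = 1)
      fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              nthread = 1),
                                data = dtr, nrounds = 50)
      as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1)))
    },
    knn = {
      k <- 15
      pr <- class::knn(x[tr, , drop = FALSE], x, y[tr], k = k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "diabetic", win, 1 - win)
    })

  label <- ifelse(prob >= 0.5, "diabetic", "non-diabetic")
  results <- data.frame(patient_id = patients$patient_id,
                        probability = as.numeric(prob), label = label,
                        split = ifelse(tr, "train", "test"),
                        stringsAsFactors = FALSE)
  metrics <- classification_metrics(label[!tr],
                                    as.character(patients$label)[!tr])
  list(results = results, metrics = metrics, model_choice = model_choice)
}
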