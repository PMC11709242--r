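# Metrics and data splitting.

#' Root mean square error
#'
#' `sqrt(mean((actual - predicted)^2))`. For predictions in `[0,1]` against
#' binary actuals the value lies in `[0,1]`.
#'
#' @param predicted numeric vector of predictions.
#' @param actual numeric vector of the same length.
#' @return non-negative scalar.
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) == 0) stop("rmse of empty input is undefined")
  if (length(predicted) != length(actual)) stop("length mismatch")
  sqrt(mean((actual - predicted)^2))
}

#' Confusion-matrix classification metrics
#'
#' Positive class is `"diabetic"` (or 1 for numeric labels). Metrics that
#' are undefined because the truth contains a single class are returned as
#' `NA` with a warning, never silently as 0.
#'
#' @param predicted,truth label vectors (character `diabetic`/`non-diabetic`
#'   or binary 0/1), equal length.
#' @return named list: `accuracy`, `precision`, `recall`, `f1`,
#'   `specificity`, plus the counts `tp`, `fp`, `fn`, `tn`.
#' @export
classification_metrics <- function(predicted, truth) {
  to_bin <- function(x) {
    if (is.character(x) || is.factor(x)) as.integer(as.character(x) == "diabetic")
    else as.integer(x)
  }
  p <- to_bin(predicted); y <- to_bin(truth)
  if (length(p) != length(y)) stop("length mismatch")
  if (!all(c(p, y) %in% c(0, 1))) stop("labels must be binary")
  tp <- sum(p == 1 & y == 1); fp <- sum(p == 1 & y == 0)
  fn <- sum(p == 0 & y == 1); tn <- sum(p == 0 & y == 0)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (empty denominator); returning NA", what))
      NA_real_
    } else num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  specificity <- safe(tn, tn + fp, "specificity")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / length(y), precision = precision,
       recall = recall, f1 = f1, specificity = specificity,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Per-user holdout split of observed ratings
#'
#' For each user, `floor(test_fraction * n_observed)` of their observed
#' entries are moved to the test mask, always leaving at least one training
#' entry. The two masks are disjoint and their union is the observed mask.
#'
#' @param ratings a [ratings_matrix()].
#' @param test_fraction fraction of each user's observations held out.
#' @param seed integer seed.
#' @return list with `train` (a [ratings_matrix()] restricted to the train
#'   mask), `train_mask`, `test_mask` (logical matrices) and `values` (the
#'   full rating value matrix, for scoring held-out entries).
#' @export
split_ratings <- function(ratings, test_fraction = 0.2, seed = 7) {
  stopifnot(inherits(ratings, "ratings_matrix"),
            test_fraction >= 0, test_fraction < 1)
  set.seed(as.integer(seed))
  obs <- ratings$observed
  test_mask <- matrix(FALSE, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  for (u in seq_len(nrow(obs))) {
    idx <- which(obs[u, ])
    n_test <- min(floor(test_fraction * length(idx)), length(idx) - 1L)
    if (n_test > 0) test_mask[u, sample(idx, n_test)] <- TRUE
  }
  train_mask <- obs & !test_mask
  train <- ratings_matrix(ratings$values * train_mask, train_mask,
                          ratings$user_ids, ratings$item_ids)
  list(train = train, train_mask = train_mask, test_mask = test_mask,
       values = ratings$values)
}

#' Write a per-epoch training-curve CSV
#'
#' One row per epoch: `epoch`, `train_rmse`, `test_rmse` — the data behind
#' learning-curve figures.
#'
#' @param trace data.frame as produced by [crbm_train()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_curves <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
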