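# Domain containers and dataset-merge preprocessing.

#' Construct a binary ratings matrix with an observation mask
#'
#' The central container for user-food ratings: a dense `{0,1}` matrix plus a
#' logical mask saying which cells were actually observed. Values in
#' unobserved cells are stored as 0 but carry no meaning; every consumer of
#' the class must go through the mask.
#'
#' @param values numeric matrix in `{0,1}` (users x items).
#' @param observed logical matrix, same shape; `TRUE` where a rating exists.
#' @param user_ids,item_ids character vectors of row/column identifiers.
#' @return An object of class `ratings_matrix` with elements `values`,
#'   `observed`, `user_ids`, `item_ids`.
#' @export
ratings_matrix <- function(values, observed, user_ids = rownames(values),
                           item_ids = colnames(values)) {
  values <- as.matrix(values)
  observed <- as.matrix(observed)
  storage.mode(observed) <- "logical"
  if (!identical(dim(values), dim(observed)))
    stop("values and observed must have identical dimensions")
  if (is.null(user_ids)) user_ids <- paste0("u", seq_len(nrow(values)))
  if (is.null(item_ids)) item_ids <- paste0("f", seq_len(ncol(values)))
  user_ids <- as.character(user_ids)
  item_ids <- as.character(item_ids)
  if (anyDuplicated(user_ids) || anyDuplicated(item_ids))
    stop("user_ids and item_ids must be unique")
  obs_vals <- values[observed]
  if (length(obs_vals) && !all(obs_vals %in% c(0, 1)))
    stop("observed ratings must be binary (0/1)")
  if (nrow(values) > 0 && any(rowSums(observed) == 0))
    stop("every user must have at least one observed rating")
  values[!observed] <- 0
  dimnames(values) <- dimnames(observed) <- list(user_ids, item_ids)
  structure(list(values = values, observed = observed,
                 user_ids = user_ids, item_ids = item_ids),
            class = "ratings_matrix")
}

#' @export
print.ratings_matrix <- function(x, ...) {
  cat(sprintf("<ratings_matrix> %d users x %d items, %d observed (density %.3f)\n",
              length(x$user_ids), length(x$item_ids), sum(x$observed),
              mean(x$observed)))
  invisible(x)
}

#' @export
dim.ratings_matrix <- function(x) dim(x$values)

#' Validate and assemble ratings from long-format rows
#'
#' Takes `(user, item, rating)` rows, deduplicates them (last write wins,
#' with a warning), optionally binarizes graded ratings, and builds a
#' [ratings_matrix()]. A graded rating `r` on a scale with maximum
#' `max_scale` is mapped to 1 when `r / max_scale >= threshold`.
#'
#' @param rows data.frame with columns `user_id`, `food_id`, `rating` (other
#'   column names are accepted positionally).
#' @param threshold optional binarization threshold on the `[0,1]` scale
#'   (default 0.5 when `max_scale` is given).
#' @param max_scale maximum of the grading scale for non-binary input.
#' @return A [ratings_matrix()].
#' @export
validate_ratings <- function(rows, threshold = NULL, max_scale = NULL) {
  rows <- as.data.frame(rows)
  if (ncol(rows) < 3) stop("ratings rows need user, item and rating columns")
  names(rows)[1:3] <- c("user_id", "food_id", "rating")
  rows$user_id <- as.character(rows$user_id)
  rows$food_id <- as.character(rows$food_id)
  r <- as.numeric(rows$rating)
  if (anyNA(r)) stop("ratings must be numeric")
  if (!all(r %in% c(0, 1))) {
    if (is.null(max_scale))
      stop("non-binary ratings require max_scale (and optionally threshold)")
    if (is.null(threshold)) threshold <- 0.5
    r <- as.numeric(r / max_scale >= threshold)
  }
  rows$rating <- r
  key <- paste(rows$user_id, rows$food_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate (user,item) pairs; keeping last occurrence",
                    sum(duplicated(key))))
    rows <- rows[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  users <- unique(rows$user_id)
  items <- unique(rows$food_id)
  vals <- matrix(0, length(users), length(items), dimnames = list(users, items))
  obs <- matrix(FALSE, length(users), length(items), dimnames = list(users, items))
  idx <- cbind(match(rows$user_id, users), match(rows$food_id, items))
  vals[idx] <- rows$rating
  obs[idx] <- TRUE
  ratings_matrix(vals, obs, users, items)
}

#' Merge branded/base food tables with nutrient links into one food table
#'
#' Reproduces the preprocessing join: branded and base food rows are combined
#' on `food_id` (inner join; branded name/price win where both are present),
#' nutrient links are resolved against the nutrient dictionary on
#' `nutrient_id`, and the result is keyed by the global food id. Rows lacking
#' a join partner are dropped and counted in the `dropped` attribute;
#' extraneous non-key columns are removed.
#'
#' @param branded,base data.frames with columns `food_id`, `name`, `price`.
#' @param food_nutrient data.frame `(food_id, nutrient_id, amount)`.
#' @param nutrient_dict data.frame `(nutrient_id, name, unit)`.
#' @return A `food_table`: data.frame `(food_id, name, price)` with a
#'   `nutrients` attribute (foods x nutrients amount matrix, per 100 g) and a
#'   `nutrient_units` attribute.
#' @export
merge_food_tables <- function(branded, base, food_nutrient, nutrient_dict) {
  need <- function(df, cols, what) {
    df <- as.data.frame(df)
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("schema error: %s is missing column(s) %s", what,
                   paste(miss, collapse = ", ")))
    df[cols]
  }
  branded <- need(branded, c("food_id", "name", "price"), "branded")
  base <- need(base, c("food_id", "name", "price"), "base")
  food_nutrient <- need(food_nutrient, c("food_id", "nutrient_id", "amount"),
                        "food_nutrient")
  nutrient_dict <- need(nutrient_dict, c("nutrient_id", "name", "unit"),
                        "nutrient_dict")
  bad <- setdiff(food_nutrient$nutrient_id, nutrient_dict$nutrient_id)
  if (length(bad))
    stop(sprintf("schema error: nutrient_id %s absent from nutrient dictionary",
                 paste(bad, collapse = ", ")))

  branded$food_id <- as.character(branded$food_id)
  base$food_id <- as.character(base$food_id)
  keep_ids <- intersect(branded$food_id, base$food_id)
  dropped_foods <- (nrow(branded) - sum(branded$food_id %in% keep_ids)) +
    (nrow(base) - sum(base$food_id %in% keep_ids))
  b1 <- branded[match(keep_ids, branded$food_id), ]
  b2 <- base[match(keep_ids, base$food_id), ]
  foods <- data.frame(food_id = keep_ids,
                      name = ifelse(is.na(b1$name) | b1$name == "",
                                    b2$name, b1$name),
                      price = ifelse(is.na(b1$price), b2$price, b1$price),
                      stringsAsFactors = FALSE)
  if (any(foods$price < 0, na.rm = TRUE)) stop("prices must be non-negative")

  fn <- food_nutrient
  fn$food_id <- as.character(fn$food_id)
  in_foods <- fn$food_id %in% foods$food_id
  dropped_links <- sum(!in_foods)
  fn <- fn[in_foods, , drop = FALSE]
  if (any(fn$amount < 0, na.rm = TRUE)) stop("nutrient amounts must be >= 0")

  nn <- nutrient_dict$name[match(fn$nutrient_id, nutrient_dict$nutrient_id)]
  nut_names <- unique(nutrient_dict$name)
  nutr <- matrix(0, nrow(foods), length(nut_names),
                 dimnames = list(foods$food_id, nut_names))
  if (nrow(fn)) nutr[cbind(match(fn$food_id, foods$food_id),
                           match(nn, nut_names))] <- fn$amount
  units <- stats::setNames(nutrient_dict$unit, nutrient_dict$name)

  if (nrow(foods) == 0)
    warning("merge produced an empty food table (no shared food_id)")
  structure(foods, nutrients = nutr, nutrient_units = units,
            dropped = c(foods = dropped_foods, nutrient_links = dropped_links),
            class = c("food_table", "data.frame"))
}

#' Nutrient amount matrix of a food table
#' @param foods a `food_table`.
#' @return numeric matrix, foods x nutrients (amount per 100 g).
#' @export
food_nutrients <- function(foods) attr(foods, "nutrients")

#' Validate a patient pathology report table
#'
#' Exactly seven real-valued pathology features per patient, plus age, sex
#' and an optional diabetic/non-diabetic label.
#'
#' @param rows data.frame with columns `patient_id`, seven feature columns,
#'   `age`, `sex` (`"female"`/`"male"`), `label`
#'   (`"diabetic"`/`"non-diabetic"`/`NA`).
#' @return the validated data.frame (invisibly classed `patient_report`).
#' @export
validate_patients <- function(rows) {
  rows <- as.data.frame(rows)
  fixed <- c("patient_id", "age", "sex", "label")
  miss <- setdiff(fixed, names(rows))
  if (length(miss))
    stop("patient table missing column(s): ", paste(miss, collapse = ", "))
  feats <- setdiff(names(rows), fixed)
  if (length(feats) != 7)
    stop(sprintf("expected exactly 7 pathology features, found %d",
                 length(feats)))
  if (!all(vapply(rows[feats], is.numeric, TRUE)))
    stop("pathology features must be numeric")
  if (any(rows$age <= 0)) stop("age must be positive")
  if (!all(rows$sex %in% c("female", "male"))) stop("sex must be female/male")
  if (!all(is.na(rows$label) | rows$label %in% c("diabetic", "non-diabetic")))
    stop("label must be diabetic/non-diabetic or NA")
  structure(rows, feature_cols = feats,
            class = c("patient_report", "data.frame"))
}

#' One-hot preference flags
#'
#' Each pair (`min_rating`/`max_rating`, `min_price`/`max_price`) must be
#' one-hot; the flags only re-order ties among equally-probable foods.
#'
#' @param min_rating,max_rating,min_price,max_price each 0 or 1.
#' @return a `preference_flags` list.
#' @export
preference_flags <- function(min_rating = 0, max_rating = 1,
                             min_price = 1, max_price = 0) {
  f <- c(min_rating = min_rating, max_rating = max_rating,
         min_price = min_price, max_price = max_price)
  if (!all(f %in% c(0, 1))) stop("preference flags must be 0/1")
  if (min_rating + max_rating != 1 || min_price + max_price != 1)
    stop("preference flag pairs must be one-hot")
  structure(as.list(f), class = "preference_flags")
}
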