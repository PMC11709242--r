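# Nutrition-requirement inference and the diet/exercise recommendation
# rules: price window, deficit coverage, percent bins on the predicted
# probability, the top-10 display cap, and a greedy kcal exercise fill.

#' Read a reference daily-intake table
#'
#' YAML schema: a `nutrients` list whose entries carry `nutrient`, `unit`
#' and `requirements` rows of `(sex, age_min, age_max, daily)`. The table
#' shipped with the package (`rda_synthetic.yaml`) is synthetic and
#' non-clinical: round numbers of the right magnitude for testing, not
#' dietary guidance.
#'
#' @param path YAML file; defaults to the shipped synthetic table.
#' @return data.frame `(nutrient, unit, sex, age_min, age_max, daily)`.
#' @export
read_requirements <- function(path = system.file("extdata",
                                                 "rda_synthetic.yaml",
                                                 package = "dietrbm")) {
  raw <- yaml::read_yaml(path)
  rows <- do.call(rbind, lapply(raw$nutrients, function(n) {
    do.call(rbind, lapply(n$requirements, function(r)
      data.frame(nutrient = n$nutrient, unit = n$unit, sex = r$sex,
                 age_min = r$age_min, age_max = r$age_max, daily = r$daily,
                 stringsAsFactors = FALSE)))
  }))
  if (any(rows$daily <= 0)) stop("required_daily must be positive")
  # age bands must not overlap within a nutrient/sex
  by_ns <- split(rows, paste(rows$nutrient, rows$sex))
  for (g in by_ns) {
    g <- g[order(g$age_min), ]
    if (nrow(g) > 1 && any(g$age_max[-nrow(g)] > g$age_min[-1]))
      stop("overlapping age bands in requirement table")
  }
  rows
}

#' Per-nutrient daily deficits for one patient
#'
#' Looks up the reference requirement for the patient's sex and age band
#' (bands are `[age_min, age_max)`), subtracts the estimated current intake
#' (0 when no diary is supplied) and floors at 0.
#'
#' @param report one patient row (from a `patient_report` data.frame).
#' @param reference requirement table from [read_requirements()].
#' @param intake optional named vector of estimated current daily intake per
#'   nutrient.
#' @return named numeric vector of deficits, one per reference nutrient.
#' @export
compute_requirements <- function(report, reference, intake = NULL) {
  sex <- report$sex[1]; age <- report$age[1]
  out <- numeric(0)
  for (nut in unique(reference$nutrient)) {
    band <- reference[reference$nutrient == nut & reference$sex == sex &
                        reference$age_min <= age & age < reference$age_max, ]
    if (nrow(band) == 0)
      stop(sprintf("no requirement covers nutrient %s, sex %s, age %s",
                   nut, sex, age))
    cur <- if (!is.null(intake) && nut %in% names(intake)) intake[[nut]] else 0
    out[nut] <- max(0, band$daily[1] - cur)
  }
  out
}

.bin_probability <- function(p) {
  b <- round(100 * p)
  ifelse(b >= 100, 100,
         ifelse(b >= 90, 90, ifelse(b >= 80, 80, ifelse(b >= 70, 70, NA))))
}

#' Rank foods into a recommendation set
#'
#' Applies the inference rules to one patient's predicted food
#' probabilities: (1) drop foods priced outside `price_range`; (2) drop
#' foods contributing to no positive-deficit nutrient; (3) bin the rest by
#' the rounded percentage of the predicted probability — 100, 90–99, 80–89,
#' 70–79; anything lower is dropped; (4) order by probability descending
#' with preference flags re-ordering ties (price flags order by price,
#' rating flags by the supplied popularity score), final tie-break food_id
#' ascending; (5) display at most 10 foods from the 100 bin.
#'
#' @param deficits named deficit vector from [compute_requirements()].
#' @param foods a `food_table`.
#' @param predictions named probability vector covering every candidate food.
#' @param prefs a [preference_flags()].
#' @param price_range numeric `c(lo, hi)`.
#' @param popularity optional named per-food popularity used by the rating
#'   preference flags.
#' @param patient_id identifier recorded in the output.
#' @return `recommendation_set`: list with `items` (data.frame `food_id`,
#'   `probability`, `bin`, `price`, `covered_nutrients`), `display` (the
#'   capped 100-bin food ids), `reasons` (structured drop counts) and
#'   `patient_id`. Empty candidate sets yield an empty set with reason
#'   codes, not an error.
#' @export
recommend <- function(deficits, foods, predictions, prefs = preference_flags(),
                      price_range = c(0, Inf), popularity = NULL,
                      patient_id = NA_character_) {
  stopifnot(inherits(foods, "food_table"), length(price_range) == 2)
  fid <- foods$food_id
  missing_pred <- setdiff(fid, names(predictions))
  if (length(missing_pred))
    stop("predictions missing for food(s): ",
         paste(utils::head(missing_pred, 5), collapse = ", "))
  p <- as.numeric(predictions[fid])
  nutr <- food_nutrients(foods)
  reasons <- c(price_filter = 0L, no_deficit_coverage = 0L, below_70 = 0L)

  keep <- foods$price >= price_range[1] & foods$price <= price_range[2]
  reasons["price_filter"] <- sum(!keep)

  want <- names(deficits)[deficits > 0]
  covers <- if (length(want))
    rowSums(nutr[, intersect(want, colnames(nutr)), drop = FALSE] > 0) > 0
  else rep(FALSE, nrow(nutr))
  reasons["no_deficit_coverage"] <- sum(keep & !covers)
  keep <- keep & covers

  bin <- .bin_probability(p)
  reasons["below_70"] <- sum(keep & is.na(bin))
  keep <- keep & !is.na(bin)

  items <- data.frame(food_id = fid[keep], probability = p[keep],
                      bin = bin[keep], price = foods$price[keep],
                      stringsAsFactors = FALSE)
  items$covered_nutrients <- apply(
    nutr[keep, intersect(want, colnames(nutr)), drop = FALSE] > 0, 1,
    function(z) paste(names(z)[z], collapse = ";"))

  # ordering: probability desc, then preference-driven tie keys, food_id asc
  pop <- if (is.null(popularity)) rep(0, nrow(items))
         else as.numeric(popularity[items$food_id])
  pop_key <- if (prefs$max_rating == 1) -pop else pop
  price_key <- if (prefs$min_price == 1) items$price else -items$price
  ord <- order(-items$probability, pop_key, price_key, items$food_id)
  items <- items[ord, , drop = FALSE]
  rownames(items) <- NULL

  display <- utils::head(items$food_id[items$bin == 100], 10)
  structure(list(patient_id = patient_id, items = items, display = display,
                 reasons = reasons),
            class = "recommendation_set")
}

#' @export
print.recommendation_set <- function(x, ...) {
  cat(sprintf("<recommendation_set> patient %s: %d foods (bins: %s); display %d\n",
              x$patient_id, nrow(x$items),
              paste(sprintf("%d%%=%d", c(100, 90, 80, 70),
                            vapply(c(100, 90, 80, 70),
                                   function(b) sum(x$items$bin == b), 0L)),
                    collapse = ", "),
              length(x$display)))
  invisible(x)
}

#' Default activity catalog
#'
#' Typical energy-expenditure rates (kcal/minute) for a small set of
#' activities; synthetic convenience values.
#' @return data.frame `(activity, kcal_per_min)`.
#' @export
default_activity_catalog <- function() {
  data.frame(activity = c("running", "swimming", "cycling", "brisk walking",
                          "yoga"),
             kcal_per_min = c(10, 9, 8, 4, 3), stringsAsFactors = FALSE)
}

#' Greedy daily exercise plan
#'
#' Fills `target_kcal` with the highest-rate activities first, at most 60
#' minutes each; minutes are the remaining kcal divided by the rate, rounded
#' up. If every activity is capped before the target is met, the shortfall
#' is flagged.
#'
#' @param target_kcal daily energy to expend (>= 0).
#' @param catalog data.frame `(activity, kcal_per_min)`, non-empty.
#' @return data.frame `(activity, minutes, kcal)` with attribute
#'   `shortfall_kcal` (0 when the target is met).
#' @export
exercise_plan <- function(target_kcal, catalog = default_activity_catalog()) {
  stopifnot(nrow(catalog) >= 1, target_kcal >= 0)
  catalog <- catalog[order(-catalog$kcal_per_min, catalog$activity), ]
  remaining <- target_kcal
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    if (remaining <= 0) break
    rate <- catalog$kcal_per_min[i]
    minutes <- min(60, ceiling(remaining / rate))
    rows[[length(rows) + 1L]] <- data.frame(activity = catalog$activity[i],
                                            minutes = minutes,
                                            kcal = minutes * rate,
                                            stringsAsFactors = FALSE)
    remaining <- remaining - minutes * rate
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(activity = character(0), minutes = numeric(0),
                         kcal = numeric(0))
  attr(out, "shortfall_kcal") <- max(0, remaining)
  out
}
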