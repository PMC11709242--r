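# Synthetic fixtures: grouped ratings, food composition tables, patient
# cohorts. Generators are pure functions of their arguments; a single integer
# seed governs all draws.

#' Specification for the grouped-ratings generator
#'
#' @param n_users,n_items,n_groups counts; `n_groups <= n_users`.
#' @param obs_density fraction of (user,item) cells observed, in (0,1].
#' @param flip_noise probability that an observed rating disagrees with the
#'   user's group prototype, in \[0, 0.5\].
#' @param seed integer seed.
#' @return a validated `ratings_gen_spec` list.
#' @export
ratings_gen_spec <- function(n_users = 500, n_items = 200, n_groups = 5,
                             obs_density = 0.3, flip_noise = 0.05, seed = 42) {
  stopifnot(n_users >= 1, n_items >= 1, n_groups >= 1, n_groups <= n_users,
            obs_density > 0, obs_density <= 1,
            flip_noise >= 0, flip_noise <= 0.5)
  structure(list(n_users = n_users, n_items = n_items, n_groups = n_groups,
                 obs_density = obs_density, flip_noise = flip_noise,
                 seed = as.integer(seed)),
            class = "ratings_gen_spec")
}

#' Generate a ratings matrix with planted user-group structure
#'
#' Users are assigned to groups; each group has a latent binary item-
#' preference prototype drawn Bernoulli(0.5). A user's rating of an item is
#' the prototype value XOR Bernoulli(`flip_noise`); the observation mask is
#' i.i.d. Bernoulli(`obs_density`) (each user forced to keep at least one
#' observation). This emulates the "users who tasted the same dishes"
#' structure that motivates per-group model training.
#'
#' @param spec a [ratings_gen_spec()].
#' @return list with `ratings` ([ratings_matrix()]), `groups` (integer truth
#'   labels per user) and `prototypes` (n_groups x n_items binary matrix).
#' @export
generate_ratings <- function(spec = ratings_gen_spec()) {
  stopifnot(inherits(spec, "ratings_gen_spec"))
  set.seed(spec$seed)
  n <- spec$n_users; m <- spec$n_items; g <- spec$n_groups
  groups <- rep_len(seq_len(g), n)
  prototypes <- matrix(stats::rbinom(g * m, 1, 0.5), g, m)
  full <- prototypes[groups, , drop = FALSE]
  flips <- matrix(stats::rbinom(n * m, 1, spec$flip_noise), n, m)
  vals <- (full + flips) %% 2
  obs <- matrix(stats::runif(n * m) < spec$obs_density, n, m)
  none <- which(rowSums(obs) == 0)
  for (u in none) obs[u, sample.int(m, 1)] <- TRUE
  rm <- ratings_matrix(vals * obs, obs,
                       sprintf("u%03d", seq_len(n)), sprintf("f%03d", seq_len(m)))
  list(ratings = rm, groups = groups, prototypes = prototypes)
}

# Table-style six compositional elements used when n_nutrients == 6.
.six_elements <- c("Potassium", "Calcium", "Fiber", "Protein", "Fat", "Iron")

#' Generate a merged food composition table
#'
#' Prices are log-uniform; each nutrient is present (amount > 0) in at least
#' 10% of foods, with log-normal amounts. With `n_nutrients = 6` the six
#' classic compositional elements (Potassium, Calcium, Fiber, Protein, Fat,
#' Iron) are used as names.
#'
#' @param n_items,n_nutrients counts (>= 1).
#' @param seed integer seed.
#' @return a `food_table` (see [merge_food_tables()]).
#' @export
generate_food_tables <- function(n_items, n_nutrients = 6, seed = 1) {
  stopifnot(n_items >= 1, n_nutrients >= 1)
  set.seed(as.integer(seed))
  ids <- sprintf("f%03d", seq_len(n_items))
  prices <- exp(stats::runif(n_items, log(0.5), log(50)))
  nn <- if (n_nutrients == 6) .six_elements
        else sprintf("Nutrient%02d", seq_len(n_nutrients))
  present_p <- stats::runif(n_nutrients, 0.2, 0.8)
  nutr <- matrix(0, n_items, n_nutrients, dimnames = list(ids, nn))
  for (k in seq_len(n_nutrients)) {
    pres <- stats::runif(n_items) < present_p[k]
    need <- ceiling(0.1 * n_items) - sum(pres)
    if (need > 0) pres[sample(which(!pres), need)] <- TRUE
    nutr[pres, k] <- stats::rlnorm(sum(pres), meanlog = 3, sdlog = 1)
  }
  foods <- data.frame(food_id = ids,
                      name = paste("Food", sub("^f", "", ids)),
                      price = round(prices, 2), stringsAsFactors = FALSE)
  units <- stats::setNames(rep("mg", n_nutrients), nn)
  units[nn %in% c("Fiber", "Protein", "Fat")] <- "g"
  structure(foods, nutrients = nutr, nutrient_units = units,
            dropped = c(foods = 0, nutrient_links = 0),
            class = c("food_table", "data.frame"))
}

#' Generate a synthetic two-class patient cohort
#'
#' Two multivariate-normal classes over 7 pathology features with unit
#' within-class standard deviation; the class means differ by `separation`
#' SDs on every feature. Class ratio is 1:2 (diabetic : non-diabetic).
#'
#' @param n cohort size (>= 2).
#' @param separation between-class mean shift in SD units (>= 0).
#' @param seed integer seed.
#' @return a `patient_report` data.frame (see [validate_patients()]).
#' @export
generate_patients <- function(n, separation = 3, seed = 1) {
  stopifnot(n >= 2, separation >= 0)
  set.seed(as.integer(seed))
  feats <- c("glucose", "blood_pressure", "skin_thickness", "insulin",
             "bmi", "pedigree", "hba1c")
  n_pos <- max(1, round(n / 3))
  label <- c(rep("diabetic", n_pos), rep("non-diabetic", n - n_pos))
  base <- c(glucose = 100, blood_pressure = 70, skin_thickness = 20,
            insulin = 80, bmi = 25, pedigree = 0.4, hba1c = 5.5)
  x <- matrix(stats::rnorm(n * 7), n, 7, dimnames = list(NULL, feats))
  x[label == "diabetic", ] <- x[label == "diabetic", ] + separation
  x <- sweep(x, 2, base, "+")
  out <- data.frame(patient_id = sprintf("p%04d", seq_len(n)), x,
                    age = sample(21:70, n, replace = TRUE),
                    sex = sample(c("female", "male"), n, replace = TRUE),
                    label = label, stringsAsFactors = FALSE)
  out <- out[sample.int(n), ]       # shuffle class blocks
  rownames(out) <- NULL
  validate_patients(out)
}

#' Write the five canonical CSV schemas of a simulated study
#'
#' Emits `ratings.csv`, `foods.csv`, `branded_foods.csv`,
#' `food_nutrient.csv`, `nutrients.csv`, `patients.csv` and `groups.csv`
#' (truth labels) into `dir`.
#'
#' @param spec a [ratings_gen_spec()].
#' @param n_nutrients nutrient count for the food table.
#' @param n_patients cohort size.
#' @param separation patient class separation.
#' @param dir output directory (created if missing).
#' @return invisibly, the list of generated objects.
#' @export
write_simulation <- function(spec = ratings_gen_spec(), n_nutrients = 6,
                             n_patients = 300, separation = 3, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_ratings(spec)
  foods <- generate_food_tables(spec$n_items, n_nutrients, spec$seed + 1L)
  patients <- generate_patients(n_patients, separation, spec$seed + 2L)

  rm <- gen$ratings
  idx <- which(rm$observed, arr.ind = TRUE)
  ratings_long <- data.frame(user_id = rm$user_ids[idx[, 1]],
                             food_id = rm$item_ids[idx[, 2]],
                             rating = rm$values[idx])
  ratings_long <- ratings_long[order(ratings_long$user_id, ratings_long$food_id), ]
  utils::write.csv(ratings_long, file.path(dir, "ratings.csv"), row.names = FALSE)

  base <- as.data.frame(foods)[c("food_id", "name", "price")]
  utils::write.csv(base, file.path(dir, "foods.csv"), row.names = FALSE)
  utils::write.csv(base, file.path(dir, "branded_foods.csv"), row.names = FALSE)

  nutr <- food_nutrients(foods)
  units <- attr(foods, "nutrient_units")
  nid <- stats::setNames(sprintf("n%02d", seq_len(ncol(nutr))), colnames(nutr))
  nz <- which(nutr > 0, arr.ind = TRUE)
  utils::write.csv(data.frame(food_id = rownames(nutr)[nz[, 1]],
                              nutrient_id = nid[colnames(nutr)[nz[, 2]]],
                              amount = nutr[nz]),
                   file.path(dir, "food_nutrient.csv"), row.names = FALSE)
  utils::write.csv(data.frame(nutrient_id = unname(nid), name = names(nid),
                              unit = unname(units[names(nid)])),
                   file.path(dir, "nutrients.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(patients), file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(user_id = rm$user_ids, group = gen$groups),
                   file.path(dir, "groups_truth.csv"), row.names = FALSE)
  invisible(list(ratings = gen, foods = foods, patients = patients))
}
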