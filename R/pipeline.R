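# End-to-end orchestration: simulate -> preprocess -> screen -> train ->
# evaluate -> recommend. Only patients screened diabetic proceed to the
# recommender. All tabular outputs are CSV; a JSON manifest records the
# config hash, seed, versions and per-stage status, and reruns with the
# same config reproduce identical outputs.

.default_config <- function() {
  list(seed = 42,
       simulate = list(n_users = 120, n_items = 60, n_groups = 4,
                       obs_density = 0.3, flip_noise = 0.05,
                       n_patients = 150, separation = 3, n_nutrients = 6),
       inputs = NULL,
       screen = list(classifier = "rf"),
       group = list(min_overlap = 0.2),
       train = list(hidden_units = 40, learning_rate = 0.05, epochs = 20,
                    cd_k = 1, activation = "sigmoid"),
       evaluate = list(test_fraction = 0.2),
       recommend = list(price_range = c(1, 40), target_kcal = 300,
                        max_patients = 25))
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      .merge_config(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

#' Run the full screening-and-recommendation pipeline
#'
#' Stages: simulate (or load the five input CSVs), preprocess (food-table
#' merge), screen (diabetes classifier), train (grouped conditional RBM),
#' evaluate (held-out RMSE), recommend (diet + exercise for
#' screened-diabetic patients only). Any stage error halts the run with the
#' stage name recorded in the manifest.
#'
#' @param config a config list, a YAML file path, or `NULL` for the default
#'   small synthetic run. Top-level keys: `seed`, `simulate` (or `inputs`
#'   naming the CSVs), `screen`, `group`, `train`, `evaluate`, `recommend`.
#' @param out_dir artifact directory (created).
#' @return invisibly, the manifest list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = NULL, out_dir = "dietrbm_run") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(.default_config(), if (is.null(config)) list() else config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  manifest <- list(config_hash = cfg_hash, seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("dietrbm")),
                   r_version = R.version.string, stages = list())
  fail <- function(stage, err) {
    manifest$stages[[stage]] <<- list(status = "error",
                                      reason = conditionMessage(err))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(err)), call. = FALSE)
  }
  done <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(list(status = "ok"), list(...))
  }

  ## ---- simulate / load ----
  data_dir <- file.path(out_dir, "data")
  tryCatch({
    if (is.null(cfg$inputs)) {
      sim <- cfg$simulate
      write_simulation(ratings_gen_spec(sim$n_users, sim$n_items,
                                        sim$n_groups, sim$obs_density,
                                        sim$flip_noise, cfg$seed),
                       n_nutrients = sim$n_nutrients,
                       n_patients = sim$n_patients,
                       separation = sim$separation, dir = data_dir)
      paths <- list(ratings = file.path(data_dir, "ratings.csv"),
                    foods = file.path(data_dir, "foods.csv"),
                    branded_foods = file.path(data_dir, "branded_foods.csv"),
                    food_nutrient = file.path(data_dir, "food_nutrient.csv"),
                    nutrients = file.path(data_dir, "nutrients.csv"),
                    patients = file.path(data_dir, "patients.csv"))
    } else paths <- cfg$inputs
    done("simulate", inputs = unlist(paths))
  }, error = function(e) fail("simulate", e))

  ## ---- preprocess ----
  tryCatch({
    rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE)
    foods <- merge_food_tables(rd(paths$branded_foods), rd(paths$foods),
                                rd(paths$food_nutrient), rd(paths$nutrients))
    ratings <- validate_ratings(rd(paths$ratings))
    patients <- validate_patients(rd(paths$patients))
    done("preprocess", n_foods = nrow(foods), n_users = length(ratings$user_ids),
         dropped = as.list(attr(foods, "dropped")))
  }, error = function(e) fail("preprocess", e))

  ## ---- screen ----
  tryCatch({
    scr <- screen_cohort(patients, cfg$screen$classifier, seed = cfg$seed)
    utils::write.csv(scr$results, file.path(out_dir, "screening.csv"),
                     row.names = FALSE)
    done("screen", classifier = cfg$screen$classifier,
         metrics = scr$metrics[c("accuracy", "precision", "recall",
                                 "f1", "specificity")],
         n_diabetic = sum(scr$results$label == "diabetic"))
  }, error = function(e) fail("screen", e))

  ## ---- train (with checkpoint reuse) ----
  ckpt <- file.path(out_dir, "checkpoint.json")
  man_path <- file.path(out_dir, "manifest.json")
  reuse <- FALSE
  if (file.exists(ckpt) && file.exists(man_path)) {
    old <- tryCatch(jsonlite::read_json(man_path), error = function(e) NULL)
    reuse <- !is.null(old) && identical(old$config_hash, cfg_hash)
  }
  tryCatch({
    sp <- split_ratings(ratings, cfg$evaluate$test_fraction, cfg$seed)
    groups <- build_groups(sp$train, cfg$group$min_overlap)
    ctx <- context_scores(sp$train, groups)
    tc <- train_config(cfg$train$hidden_units, cfg$train$learning_rate,
                       cfg$train$epochs, cfg$train$cd_k,
                       cfg$train$activation, cfg$seed)
    if (reuse) {
      model <- load_crbm(ckpt)
      model$context <- ctx
    } else {
      model <- train_groups(sp$train, groups, tc, context = ctx,
                             heldout = list(mask = sp$test_mask,
                                            values = sp$values))
      save_crbm(model, ckpt)
      write_curves(model$trace, file.path(out_dir, "curves.csv"))
    }
    gdf <- do.call(rbind, lapply(seq_along(groups), function(k)
      data.frame(group_id = k, user_id = groups[[k]]$member_ids)))
    utils::write.csv(gdf, file.path(out_dir, "groups.csv"), row.names = FALSE)
    done("train", n_groups = length(groups), epochs = cfg$train$epochs,
         reused_checkpoint = reuse)
  }, error = function(e) fail("train", e))

  ## ---- evaluate ----
  tryCatch({
    pred <- predict_matrix(model$params, sp$train, model$context,
                            cfg$train$activation)
    held <- if (any(sp$test_mask))
      rmse(pred[sp$test_mask], sp$values[sp$test_mask]) else NA_real_
    done("evaluate", heldout_rmse = held,
         train_rmse = rmse(pred[sp$train_mask], sp$values[sp$train_mask]))
  }, error = function(e) fail("evaluate", e))

  ## ---- recommend (diabetic patients only) ----
  tryCatch({
    ref <- read_requirements()
    pop <- popularity_scores(sp$train)
    keep <- foods$food_id %in% colnames(pred)
    foods <- structure(as.data.frame(foods)[keep, , drop = FALSE],
                       nutrients = food_nutrients(foods)[keep, , drop = FALSE],
                       nutrient_units = attr(foods, "nutrient_units"),
                       class = c("food_table", "data.frame"))
    diab <- scr$results$patient_id[scr$results$label == "diabetic"]
    diab <- utils::head(diab, cfg$recommend$max_patients)
    rec_rows <- list(); ex_rows <- list()
    users <- sp$train$user_ids
    for (i in seq_along(diab)) {
      prow <- patients[patients$patient_id == diab[i], ]
      defs <- compute_requirements(prow, ref)
      # synthetic linkage: patient i borrows the rating history of user
      # (i mod n_users) for preference prediction
      u <- users[((i - 1L) %% length(users)) + 1L]
      preds <- pred[u, ]
      rs <- recommend(defs, foods, preds,
                      price_range = unlist(cfg$recommend$price_range),
                      popularity = pop, patient_id = diab[i])
      if (nrow(rs$items))
        rec_rows[[i]] <- cbind(patient_id = diab[i],
                               rs$items[c("food_id", "probability", "bin",
                                          "price", "covered_nutrients")])
      ep <- exercise_plan(cfg$recommend$target_kcal)
      ex_rows[[i]] <- cbind(patient_id = diab[i], ep)
    }
    recs <- if (length(rec_rows)) do.call(rbind, rec_rows)
            else data.frame(patient_id = character(0), food_id = character(0),
                            probability = numeric(0), bin = integer(0),
                            price = numeric(0),
                            covered_nutrients = character(0))
    utils::write.csv(recs, file.path(out_dir, "recommendations.csv"),
                     row.names = FALSE)
    utils::write.csv(if (length(ex_rows)) do.call(rbind, ex_rows)
                     else data.frame(),
                     file.path(out_dir, "exercise.csv"), row.names = FALSE)
    summ <- as.data.frame(table(bin = factor(recs$bin,
                                             levels = c(100, 90, 80, 70))))
    names(summ) <- c("bin", "n_foods")
    utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    done("recommend", n_patients = length(diab),
         gated_out = sum(scr$results$label == "non-diabetic"),
         empty_cohort = length(diab) == 0)
  }, error = function(e) fail("recommend", e))

  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
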