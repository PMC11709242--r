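# Per-group training with a shared global parameter store. Users who rated
# overlapping item sets are grouped; each group trains a conditional RBM
# over its own visible subset (sub-weight matrix rows), and groups run
# sequentially per epoch against the same store, so later groups see
# earlier groups' updates. Within a group an epoch is a sequential pass of
# per-case contrastive-divergence updates (one user at a time, applied
# immediately), so the expected step size is independent of group size.

#' Group users by overlapping rated-item sets
#'
#' Greedy agglomeration: seed a new group with the unassigned user holding
#' the most ratings (ties: first in user order); scan the remaining
#' unassigned users in order and absorb any whose rated-item Jaccard overlap
#' with the group's current item union is at least `min_overlap`, growing
#' the union as members join. Deterministic; singleton groups are allowed.
#'
#' @param ratings a [ratings_matrix()].
#' @param min_overlap Jaccard threshold in (0, 1].
#' @return list of `user_group` objects, each with `member_ids`,
#'   `item_subset` (item ids: union of members' observed items) and
#'   `index_map` (positions of `item_subset` in the global item vector).
#' @export
build_groups <- function(ratings, min_overlap = 0.2) {
  stopifnot(inherits(ratings, "ratings_matrix"),
            min_overlap > 0, min_overlap <= 1)
  obs <- ratings$observed
  n <- nrow(obs)
  item_sets <- lapply(seq_len(n), function(u) which(obs[u, ]))
  counts <- vapply(item_sets, length, 0L)
  unassigned <- seq_len(n)
  groups <- list()
  while (length(unassigned)) {
    seed <- unassigned[which.max(counts[unassigned])]
    members <- seed
    union_items <- item_sets[[seed]]
    for (u in setdiff(unassigned, seed)) {
      s <- item_sets[[u]]
      jac <- length(intersect(s, union_items)) / length(union(s, union_items))
      if (jac >= min_overlap) {
        members <- c(members, u)
        union_items <- union(union_items, s)
      }
    }
    union_items <- sort(union_items)
    groups[[length(groups) + 1L]] <- structure(
      list(member_ids = ratings$user_ids[members],
           item_subset = ratings$item_ids[union_items],
           index_map = union_items),
      class = "user_group")
    unassigned <- setdiff(unassigned, members)
  }
  groups
}

.zero_context <- function(ratings) {
  list(S = matrix(0, nrow(ratings$values), ncol(ratings$values),
                  dimnames = dimnames(ratings$values)),
       P = stats::setNames(numeric(length(ratings$item_ids)),
                           ratings$item_ids))
}

# One epoch of sequential per-case CD updates for every group, mutating the
# global store. Inlined single-case arithmetic identical to
# cd_update(batch of one) — same statistics, same RNG draw order.
.epoch_pass <- function(params, groups, vobs, obs, S, P, config) {
  eps <- config$learning_rate
  f <- ncol(params$R)
  relu_act <- config$activation == "relu"
  for (g in groups) {
    members <- g$members_idx
    sub <- g$index_map
    if (length(members) == 0) next
    # group-local working copies: only this group touches these rows during
    # its sequential pass, so copy-in/copy-out is exact
    Rg <- params$R[sub, , drop = FALSE]
    Swg <- params$Sw[sub, , drop = FALSE]
    Twg <- params$Tw[sub, , drop = FALSE]
    ag <- params$a; bg <- params$b[sub]
    p <- P[sub]
    for (u in members) {
      v <- vobs[u, sub]; o <- obs[u, sub]
      s <- S[u, sub]
      pre <- ag + as.numeric(v %*% Rg + s %*% Swg + p %*% Twg)
      h_prob <- 1 / (1 + exp(-pre))
      h_data <- if (relu_act) pmax(0, pre) else h_prob
      h_samp <- (stats::runif(f) < h_prob) * 1
      for (t in seq_len(config$cd_k)) {
        v_prob <- 1 / (1 + exp(-(bg + as.numeric(Rg %*% h_samp))))
        v_neg <- (stats::runif(length(sub)) < v_prob) * o
        pre_n <- ag + as.numeric(v_neg %*% Rg + s %*% Swg + p %*% Twg)
        h_neg <- if (relu_act) pmax(0, pre_n) else 1 / (1 + exp(-pre_n))
        if (t < config$cd_k)
          h_samp <- (stats::runif(f) < 1 / (1 + exp(-pre_n))) * 1
      }
      Rg <- Rg + eps * (outer(v, h_data) - outer(v_neg, h_neg))
      Swg <- Swg + eps * outer(s, h_data - h_neg)
      Twg <- Twg + eps * outer(p, h_data - h_neg)
      ag <- ag + eps * (h_data - h_neg)
      bg <- bg + eps * (v - v_neg)
    }
    params$R[sub, ] <- Rg
    params$Sw[sub, ] <- Swg
    params$Tw[sub, ] <- Twg
    params$a <- ag
    params$b[sub] <- bg
  }
  params
}

.train_core <- function(ratings, groups, context, config, heldout = NULL,
                        params = NULL, use_context = TRUE) {
  n_items <- length(ratings$item_ids)
  vobs <- ratings$values * ratings$observed
  obs <- ratings$observed
  if (is.null(params)) {
    n_obs <- colSums(obs)
    means <- ifelse(n_obs > 0, colSums(vobs) / pmax(n_obs, 1), NA)
    params <- init_crbm(n_items, n_items, n_items, config$hidden_units,
                        visible_means = means, seed = config$seed)
  }
  if (use_context) {
    ctx <- list(S = context$S, P = context$P)
  } else {
    params$Sw[] <- 0
    params$Tw[] <- 0
    ctx <- .zero_context(ratings)
  }
  for (k in seq_along(groups)) {
    groups[[k]]$members_idx <- match(groups[[k]]$member_ids, ratings$user_ids)
    if (length(groups[[k]]$members_idx) == 0)
      warning(sprintf("group %d is empty; skipped", k))
  }
  set.seed(config$seed + 1L)      # chain draws, after initialization
  n_g <- length(groups)
  train_rmse <- test_rmse <- rep(NA_real_, config$epochs)
  per_group <- matrix(NA_real_, config$epochs, n_g)
  best <- list(params = params, epoch = 0L, rmse = Inf)
  for (epoch in seq_len(config$epochs)) {
    params <- .epoch_pass(params, groups, vobs, obs, ctx$S, ctx$P, config)
    pred <- predict_matrix(params, ratings, ctx, config$activation)
    train_rmse[epoch] <- rmse(pred[obs], ratings$values[obs])
    if (!is.null(heldout)) {
      test_rmse[epoch] <- rmse(pred[heldout$mask], heldout$values[heldout$mask])
      if (test_rmse[epoch] < best$rmse)
        best <- list(params = params, epoch = epoch, rmse = test_rmse[epoch])
    }
    for (k in seq_len(n_g)) {
      m_obs <- obs[groups[[k]]$members_idx, , drop = FALSE]
      if (any(m_obs))
        per_group[epoch, k] <- rmse(pred[groups[[k]]$members_idx, , drop = FALSE][m_obs],
                                    ratings$values[groups[[k]]$members_idx, , drop = FALSE][m_obs])
    }
  }
  if (is.null(heldout)) best <- list(params = params, epoch = config$epochs,
                                     rmse = NA_real_)
  list(params = params, config = config,
       trace = data.frame(epoch = seq_len(config$epochs),
                          train_rmse = train_rmse, test_rmse = test_rmse),
       per_group = per_group, context = ctx,
       best_params = best$params, best_epoch = best$epoch,
       best_rmse = best$rmse)
}

#' Train per-group conditional RBMs against a shared parameter store
#'
#' Each epoch visits the groups in index order; within a group, members are
#' visited sequentially and each member contributes one per-case CD update
#' (Eqs of the update rule applied to a single data case) to the shared
#' store, touching only the rows of `R`/`Sw`/`Tw`/`b` indexed by the
#' group's item subset plus the shared hidden biases. Items rated by no
#' group member keep their initial parameters. Per-case updates keep the
#' expected step size independent of group size.
#'
#' @param ratings a [ratings_matrix()] (the training split).
#' @param groups list of `user_group`s from [build_groups()].
#' @param config a [train_config()].
#' @param context a [context_scores()]; computed from `ratings` and `groups`
#'   when omitted.
#' @param heldout optional list `(mask, values)` of held-out entries for a
#'   per-epoch test RMSE.
#' @param params optional pretrained [crbm_params()] warm start.
#' @param use_context if `FALSE`, zero and freeze the similarity/popularity
#'   weights (plain V-H model).
#' @return list with `params` (final), `best_params`/`best_epoch`/
#'   `best_rmse` (held-out optimum when `heldout` given), `config`, `trace`
#'   (epoch, train_rmse, test_rmse), `per_group` (epochs x groups RMSE
#'   matrix) and `context`.
#' @export
train_groups <- function(ratings, groups, config, context = NULL,
                         heldout = NULL, params = NULL, use_context = TRUE) {
  if (is.null(context) && use_context)
    context <- context_scores(ratings, groups)
  .train_core(ratings, groups, context, config, heldout, params, use_context)
}

#' Train one conditional RBM over the whole user set
#'
#' The degenerate single-group case of [train_groups()]: one group holding
#' every user, whose item subset is every item with at least one observed
#' rating.
#'
#' @inheritParams train_groups
#' @param context a [context_scores()].
#' @return as [train_groups()].
#' @export
crbm_train <- function(ratings, context, config, heldout = NULL,
                       params = NULL, use_context = TRUE) {
  rated <- which(colSums(ratings$observed) > 0)
  g <- structure(list(member_ids = ratings$user_ids,
                      item_subset = ratings$item_ids[rated],
                      index_map = rated),
                 class = "user_group")
  .train_core(ratings, list(g), context, config, heldout, params, use_context)
}
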