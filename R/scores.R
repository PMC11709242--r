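# Similarity and popularity context scores conditioning the hidden layer.
#
# S(u,i) = sum over neighbours x of Rating_{x,i}, divided by the neighbourhood
# size N(u); P(i) = sum over all reference users of Rating_{y,i}, divided by
# N * r_max. Both live in [0,1] for binary ratings. Unobserved entries
# contribute 0 to either sum.

#' Per-item similarity scores for one user
#'
#' Fraction of the user's neighbourhood that rated each item positively.
#' The neighbourhood is the set of other members of the user's training
#' group (the model's only grouping construct).
#'
#' @param u user id.
#' @param ratings a [ratings_matrix()].
#' @param neighborhood character vector of neighbour user ids; must be
#'   non-empty and exclude `u`.
#' @return named numeric vector over items, values in `[0,1]`.
#' @export
similarity_scores <- function(u, ratings, neighborhood) {
  stopifnot(inherits(ratings, "ratings_matrix"))
  neighborhood <- as.character(neighborhood)
  if (length(neighborhood) == 0)
    stop("empty neighbourhood: similarity is undefined (division by zero)")
  if (u %in% neighborhood) stop("neighbourhood must exclude the user")
  miss <- setdiff(neighborhood, ratings$user_ids)
  if (length(miss)) stop("unknown neighbour id(s): ", paste(miss, collapse = ", "))
  rows <- ratings$values[neighborhood, , drop = FALSE] *
    ratings$observed[neighborhood, , drop = FALSE]
  colSums(rows) / length(neighborhood)
}

#' Per-item popularity scores
#'
#' Scaled positive-rating fraction over a reference set of users (the whole
#' training split by default): `P(i) = sum_y Rating_{y,i} / (N * r_max)`.
#'
#' @param ratings a [ratings_matrix()].
#' @param r_max maximum rating scale (1 for binary ratings).
#' @param users optional subset of user ids defining the reference set.
#' @return named numeric vector over items, values in `[0,1]`.
#' @export
popularity_scores <- function(ratings, r_max = 1, users = NULL) {
  stopifnot(inherits(ratings, "ratings_matrix"), r_max >= 1)
  if (is.null(users)) users <- ratings$user_ids
  if (length(users) == 0) stop("empty reference set: popularity is undefined")
  rows <- ratings$values[users, , drop = FALSE] *
    ratings$observed[users, , drop = FALSE]
  colSums(rows) / (length(users) * r_max)
}

#' Context score matrices for all users
#'
#' Convenience wrapper building the per-user similarity matrix (each row the
#' user's [similarity_scores()] over their group co-members) and the shared
#' popularity vector, as used by the trainer and predictor.
#'
#' @param ratings a [ratings_matrix()].
#' @param groups a group assignment as returned by [build_groups()] (list of
#'   `user_group`s) or an integer/character vector of group labels per user.
#' @param r_max maximum rating scale.
#' @return list of class `context_scores` with `S` (users x items matrix) and
#'   `P` (item vector). Users whose group is a singleton get an all-zero
#'   similarity row (no neighbours carry no signal).
#' @export
context_scores <- function(ratings, groups, r_max = 1) {
  stopifnot(inherits(ratings, "ratings_matrix"))
  if (is.list(groups) && all(vapply(groups, inherits, TRUE, "user_group"))) {
    labels <- rep(NA_integer_, length(ratings$user_ids))
    names(labels) <- ratings$user_ids
    for (k in seq_along(groups)) labels[groups[[k]]$member_ids] <- k
  } else {
    labels <- stats::setNames(as.integer(factor(groups)), ratings$user_ids)
  }
  if (anyNA(labels)) stop("groups must cover every user")
  obs_vals <- ratings$values * ratings$observed
  S <- matrix(0, nrow(obs_vals), ncol(obs_vals), dimnames = dimnames(obs_vals))
  for (g in unique(labels)) {
    members <- names(labels)[labels == g]
    if (length(members) < 2) next
    tot <- colSums(obs_vals[members, , drop = FALSE])
    # each member's neighbourhood is the other members: (total - own) / (n-1)
    S[members, ] <- sweep(-obs_vals[members, , drop = FALSE], 2, tot, "+") /
      (length(members) - 1)
  }
  P <- popularity_scores(ratings, r_max)
  structure(list(S = S, P = P, group_labels = labels),
            class = "context_scores")
}
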