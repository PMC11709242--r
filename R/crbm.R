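# Conditional restricted Boltzmann machine over four binary layers:
# visible ratings V, similarity context S, popularity context P, hidden H.
# The hidden layer is fully connected to V, S and P through weight matrices
# R, Sw and Tw; there are no intra-layer connections. The joint energy is
#
#   E(V,S,P,H) = - b.V - c.S - d.P - a.H - V'R H - S'Sw H - P'Tw H
#
# whose conditionals factorize into per-unit sigmoids. S and P are treated
# as clamped, real-valued conditioning inputs during training and
# prediction; their reconstruction conditionals exist for the exact
# enumeration oracle and unclamped Gibbs sampling.

#' Logistic sigmoid
#' @param x numeric.
#' @return `1 / (1 + exp(-x))`, saturating without under/overflow warnings.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Rectified linear unit
#' @param x numeric.
#' @return `max(0, x)` elementwise.
#' @export
relu <- function(x) pmax(0, x)

#' Construct a conditional-RBM parameter store
#'
#' One global store holds the visible-hidden weights `R`, the
#' similarity-hidden weights `Sw`, the popularity-hidden weights `Tw` and the
#' bias vectors `a` (hidden), `b` (visible), `c` (similarity), `d`
#' (popularity).
#'
#' @param R,Sw,Tw weight matrices (`n_v x F`, `n_s x F`, `n_p x F`).
#' @param a,b,c,d bias vectors (hidden, visible, similarity, popularity).
#' @return object of class `crbm_params`.
#' @export
crbm_params <- function(R, Sw, Tw, a, b, c, d) {
  R <- as.matrix(R); Sw <- as.matrix(Sw); Tw <- as.matrix(Tw)
  f <- ncol(R)
  if (ncol(Sw) != f || ncol(Tw) != f)
    stop("R, Sw, Tw must share their hidden dimension")
  if (length(a) != f) stop("hidden bias length must equal ncol(R)")
  if (length(b) != nrow(R) || length(c) != nrow(Sw) || length(d) != nrow(Tw))
    stop("bias lengths must match weight-matrix rows")
  vals <- c(R, Sw, Tw, a, b, c, d)
  if (!all(is.finite(vals))) stop("parameters must be finite")
  structure(list(R = R, Sw = Sw, Tw = Tw,
                 a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d)),
            class = "crbm_params")
}

#' Initialize parameters for a model of given shape
#'
#' Weights are drawn Normal(0, `init_sd`^2); hidden biases start at 0;
#' visible biases default to the log-odds of each item's observed rating
#' mean, clipped to +/-4 (items with no observations get 0).
#'
#' @param n_v,n_s,n_p,n_hidden layer sizes.
#' @param init_sd weight initialization SD.
#' @param visible_means optional per-item observed rating means for the
#'   log-odds bias initialization.
#' @param seed integer seed.
#' @return a [crbm_params()].
#' @export
init_crbm <- function(n_v, n_s = n_v, n_p = n_v, n_hidden = 100,
                      init_sd = 0.01, visible_means = NULL, seed = 1) {
  set.seed(as.integer(seed))
  b <- numeric(n_v)
  if (!is.null(visible_means)) {
    m <- pmin(pmax(visible_means, 1e-6), 1 - 1e-6)
    b <- pmin(pmax(log(m / (1 - m)), -4), 4)
    b[is.na(visible_means)] <- 0
  }
  crbm_params(R = matrix(stats::rnorm(n_v * n_hidden, 0, init_sd), n_v),
              Sw = matrix(stats::rnorm(n_s * n_hidden, 0, init_sd), n_s),
              Tw = matrix(stats::rnorm(n_p * n_hidden, 0, init_sd), n_p),
              a = numeric(n_hidden), b = b, c = numeric(n_s), d = numeric(n_p))
}

#' Training configuration
#'
#' @param hidden_units number of hidden units F (1..200).
#' @param learning_rate positive step size epsilon (0.05 with pretrained /
#'   informative starts, 0.01 for cold starts).
#' @param epochs number of full passes.
#' @param cd_k contrastive-divergence chain length (>= 1).
#' @param activation `"sigmoid"` (default) or `"relu"`; relu rectifies hidden
#'   pre-activations for data statistics and prediction only — sampling
#'   probabilities are always sigmoid.
#' @param seed integer seed controlling initialization and all chain draws.
#' @return a `train_config` list.
#' @export
train_config <- function(hidden_units = 100, learning_rate = 0.05,
                         epochs = 50, cd_k = 1,
                         activation = c("sigmoid", "relu"), seed = 1) {
  activation <- match.arg(activation)
  if (hidden_units < 1 || hidden_units > 200)
    stop("hidden_units must be in [1, 200]")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (cd_k < 1) stop("cd_k must be >= 1")
  if (epochs < 0) stop("epochs must be >= 0")
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 cd_k = as.integer(cd_k), activation = activation,
                 seed = as.integer(seed)),
            class = "train_config")
}

.as_row <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)

#' Joint energy of a fully binary configuration
#'
#' @param v,s,p,h binary state vectors for the four layers.
#' @param params a [crbm_params()].
#' @return scalar energy; 0 when every unit is off or every parameter is 0.
#' @export
crbm_energy <- function(v, s, p, h, params) {
  if (length(v) != nrow(params$R) || length(s) != nrow(params$Sw) ||
      length(p) != nrow(params$Tw) || length(h) != ncol(params$R))
    stop("state/parameter shape mismatch")
  -sum(params$b * v) - sum(params$c * s) - sum(params$d * p) -
    sum(params$a * h) -
    as.numeric(v %*% params$R %*% h) -
    as.numeric(s %*% params$Sw %*% h) -
    as.numeric(p %*% params$Tw %*% h)
}

.enum_bits <- function(n) {
  if (n == 0) return(matrix(0, 1, 0))
  g <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(g) <- NULL
  g
}

#' Exact Boltzmann distribution by enumeration
#'
#' Enumerates every joint binary configuration of a small model and
#' normalizes `exp(-E)` by the partition function. Intended as the ground
#' truth for conditionals, marginals and sampler checks; refuses models with
#' more than 16 total units.
#'
#' @param params a [crbm_params()].
#' @return list with binary config matrices `V`, `S`, `P`, `H` (one row per
#'   joint configuration), the probability vector `prob`, and `logZ`.
#' @export
exact_distribution <- function(params) {
  nv <- nrow(params$R); ns <- nrow(params$Sw); np <- nrow(params$Tw)
  f <- ncol(params$R)
  n <- nv + ns + np + f
  if (n > 16)
    stop(sprintf("model too large for enumeration: %d units (max 16)", n))
  cfg <- .enum_bits(n)
  V <- cfg[, seq_len(nv), drop = FALSE]
  S <- cfg[, nv + seq_len(ns), drop = FALSE]
  P <- cfg[, nv + ns + seq_len(np), drop = FALSE]
  H <- cfg[, nv + ns + np + seq_len(f), drop = FALSE]
  e <- -(V %*% params$b + S %*% params$c + P %*% params$d + H %*% params$a +
           rowSums((V %*% params$R) * H) +
           rowSums((S %*% params$Sw) * H) +
           rowSums((P %*% params$Tw) * H))
  e <- as.numeric(e)
  m <- max(-e)
  w <- exp(-e - m)
  list(V = V, S = S, P = P, H = H, prob = w / sum(w), logZ = log(sum(w)) + m)
}

#' Hidden-unit conditional probabilities given clamped V, S, P
#'
#' Per-unit `sigma(a_j + sum_i V_i R_ij + sum_i S_i Sw_ij + sum_i P_i Tw_ij)`.
#' Unobserved visible items must be passed as 0 so that they contribute
#' nothing.
#'
#' @param params a [crbm_params()].
#' @param v,s,p clamped states: vectors, or matrices with one row per case.
#'   `v` binary over observed items; `s`, `p` in `[0,1]`.
#' @param activation `"sigmoid"` for probabilities, `"relu"` for rectified
#'   pre-activations (never valid as sampling probabilities).
#' @return matrix of hidden values, one row per case (vector in = vector out).
#' @export
hidden_conditional <- function(params, v, s, p, activation = "sigmoid") {
  vec_in <- !is.matrix(v)
  v <- .as_row(v); s <- .as_row(s); p <- .as_row(p)
  if (ncol(v) != nrow(params$R) || ncol(s) != nrow(params$Sw) ||
      ncol(p) != nrow(params$Tw))
    stop("state/parameter shape mismatch")
  pre <- sweep(v %*% params$R + s %*% params$Sw + p %*% params$Tw,
               2, params$a, "+")
  out <- if (activation == "relu") relu(pre) else sigmoid(pre)
  if (vec_in) out[1, ] else out
}

#' Reconstruction conditionals of V, S and P given hidden states
#'
#' Factorized per-unit sigmoids: `P(V_i=1|H) = sigma(b_i + sum_j H_j R_ij)`
#' and analogously for S (bias `c`, weights `Sw`) and P (bias `d`, weights
#' `Tw`). The V conditional involves neither `c` nor `d`.
#'
#' @param params a [crbm_params()].
#' @param h hidden state vector, or matrix with one row per case.
#' @return list of probability arrays `V`, `S`, `P` matching the input shape.
#' @export
reconstruct_conditionals <- function(params, h) {
  vec_in <- !is.matrix(h)
  h <- .as_row(h)
  if (ncol(h) != ncol(params$R)) stop("state/parameter shape mismatch")
  out <- list(V = sigmoid(sweep(h %*% t(params$R), 2, params$b, "+")),
              S = sigmoid(sweep(h %*% t(params$Sw), 2, params$c, "+")),
              P = sigmoid(sweep(h %*% t(params$Tw), 2, params$d, "+")))
  if (vec_in) lapply(out, function(m) m[1, ]) else out
}

.sample_bern <- function(prob) {
  out <- (stats::runif(length(prob)) < prob) * 1
  if (is.matrix(prob)) dim(out) <- dim(prob)
  out
}

#' Block Gibbs sampling over the joint model
#'
#' Each step samples H from its conditional given (V,S,P), then resamples
#' every unclamped layer among V, S, P from its conditional given the new H.
#' Clamped layers are never modified. Draws come from R's global RNG; seed
#' the session for reproducibility.
#'
#' @param state list with binary vectors `V`, `S`, `P`, `H`.
#' @param params a [crbm_params()].
#' @param steps number of sweeps (>= 1).
#' @param clamp character subset of `c("V","S","P","H")` to hold fixed.
#' @param record if `TRUE`, also return the state after every sweep.
#' @return final `state`; with `record`, a list `(state, trace)` where
#'   `trace` is a `steps x n_units` binary matrix of `(V,S,P,H)` rows.
#' @export
gibbs_chain <- function(state, params, steps, clamp = character(0),
                        record = FALSE) {
  stopifnot(steps >= 1)
  v <- state$V; s <- state$S; p <- state$P; h <- state$H
  trace <- if (record)
    matrix(0, steps, length(v) + length(s) + length(p) + length(h))
  for (t in seq_len(steps)) {
    if (!("H" %in% clamp))
      h <- .sample_bern(hidden_conditional(params, v, s, p))
    rec <- reconstruct_conditionals(params, h)
    if (!("V" %in% clamp)) v <- .sample_bern(rec$V)
    if (!("S" %in% clamp)) s <- .sample_bern(rec$S)
    if (!("P" %in% clamp)) p <- .sample_bern(rec$P)
    if (record) trace[t, ] <- c(v, s, p, h)
  }
  out <- list(V = v, S = s, P = p, H = h)
  if (record) list(state = out, trace = trace) else out
}

#' One contrastive-divergence parameter update from a batch
#'
#' Data phase: V (observed items), S and P are clamped; hidden probabilities
#' supply the data statistics. Negative phase: a k-step chain alternates a
#' sampled H with a sampled V reconstruction (masked to each case's observed
#' items) while S and P stay clamped. The update is
#' `delta_R = eps * (<V H>_data - <V H>_k)` with the analogous expressions
#' for `Sw`, `Tw` and the `a`, `b` biases; statistics are means over the
#' batch, so a group's gradient is automatically scaled by its member count.
#' Items unobserved in a case contribute to no delta. The clamped context
#' biases `c`, `d` receive zero deltas.
#'
#' @param params a [crbm_params()].
#' @param v data matrix (cases x items), binary, 0 where unobserved.
#' @param s,p context: matrices (cases x items) or a single shared vector.
#' @param observed logical matrix matching `v`.
#' @param config a [train_config()]; supplies `learning_rate`, `cd_k` and
#'   `activation`.
#' @return list of deltas `R`, `Sw`, `Tw`, `a`, `b`, `c`, `d` (same shapes
#'   as the parameters).
#' @export
cd_update <- function(params, v, s, p, observed, config) {
  if (config$learning_rate <= 0) stop("learning_rate must be positive")
  v <- .as_row(v)
  n <- nrow(v)
  if (n == 0) stop("batch must be non-empty")
  expand <- function(x, cols) {
    if (is.matrix(x)) x else matrix(x, n, cols, byrow = TRUE)
  }
  s <- expand(s, nrow(params$Sw))
  p <- expand(p, nrow(params$Tw))
  observed <- .as_row(observed)
  eps <- config$learning_rate

  h_data <- hidden_conditional(params, v, s, p, config$activation)
  h_samp <- .sample_bern(hidden_conditional(params, v, s, p))
  v_neg <- v
  for (t in seq_len(config$cd_k)) {
    v_prob <- sigmoid(sweep(h_samp %*% t(params$R), 2, params$b, "+"))
    v_neg <- .sample_bern(v_prob) * observed
    h_neg <- hidden_conditional(params, v_neg, s, p, config$activation)
    if (t < config$cd_k)
      h_samp <- .sample_bern(hidden_conditional(params, v_neg, s, p))
  }
  list(R = eps * (crossprod(v, h_data) - crossprod(v_neg, h_neg)) / n,
       Sw = eps * crossprod(s, h_data - h_neg) / n,
       Tw = eps * crossprod(p, h_data - h_neg) / n,
       a = eps * (colMeans(h_data) - colMeans(h_neg)),
       b = eps * (colMeans(v) - colMeans(v_neg)),
       c = numeric(nrow(params$Sw)),
       d = numeric(nrow(params$Tw)))
}

#' Predict rating probabilities for all users
#'
#' Mean-field pass: hidden activations from each user's observed ratings and
#' context scores, then `P(V_q = 1) = sigma(b_q + sum_j Hbar_j R_qj)` for
#' every item (no sampling).
#'
#' @param params a [crbm_params()] over the full item set.
#' @param ratings a [ratings_matrix()] supplying observed V.
#' @param context a [context_scores()] for the same users/items.
#' @param activation hidden transform, as in [train_config()].
#' @return users x items matrix of predicted probabilities.
#' @export
predict_matrix <- function(params, ratings, context, activation = "sigmoid") {
  v <- ratings$values * ratings$observed
  h <- hidden_conditional(params, v,
                          context$S,
                          matrix(context$P, nrow(v), length(context$P),
                                 byrow = TRUE),
                          activation)
  pred <- sigmoid(sweep(h %*% t(params$R), 2, params$b, "+"))
  dimnames(pred) <- dimnames(ratings$values)
  pred
}

#' Predict rating probabilities for one user on target items
#'
#' @param params a [crbm_params()].
#' @param v observed binary rating vector (0 where unobserved).
#' @param s,p the user's similarity vector and the popularity vector.
#' @param targets item indices or names to score. Targets that the user has
#'   already rated are still scored, with a warning.
#' @param observed optional logical vector marking which entries of `v` are
#'   real observations (default: `v` as given, all treated as the clamp).
#' @param activation hidden transform.
#' @return named probability vector over `targets`.
#' @export
predict_ratings <- function(params, v, s, p, targets,
                            observed = NULL, activation = "sigmoid") {
  nv <- nrow(params$R)
  if (length(v) != nv) stop("v has wrong length")
  if (is.character(targets)) {
    if (is.null(names(v))) stop("named targets require a named v")
    idx <- match(targets, names(v))
    if (anyNA(idx)) stop("unknown item id(s): ",
                         paste(targets[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(targets)
    if (any(idx < 1 | idx > nv)) stop("target index out of range")
  }
  if (!is.null(observed)) {
    if (any(observed[idx]))
      warning("some targets are already observed for this user")
    v <- v * observed
  }
  hbar <- hidden_conditional(params, v, s, p, activation)
  out <- sigmoid(params$b[idx] + as.numeric(params$R[idx, , drop = FALSE] %*% hbar))
  names(out) <- if (is.null(names(v))) NULL else names(v)[idx]
  out
}

#' Save / load a model checkpoint
#'
#' Plain-JSON archive holding shapes, parameters, config, seed and the RMSE
#' trace, with a `schema` version field.
#'
#' @param model a trained model list as returned by [crbm_train()] or
#'   [train_groups()] (elements `params`, `config`, `trace`).
#' @param path file path.
#' @return `save_crbm`: the path, invisibly. `load_crbm`: the model list.
#' @export
save_crbm <- function(model, path) {
  p <- model$params
  obj <- list(schema = 1L,
              shape = list(n_v = nrow(p$R), n_s = nrow(p$Sw),
                           n_p = nrow(p$Tw), n_hidden = ncol(p$R)),
              params = lapply(unclass(p), function(x)
                if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
                else list(dim = NULL, data = as.numeric(x))),
              config = unclass(model$config),
              trace = as.list(model$trace))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_crbm
#' @export
load_crbm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != 1L)
    stop("unsupported checkpoint schema")
  pr <- lapply(obj$params, function(x) {
    if (!is.null(x$dim) && length(x$dim)) matrix(x$data, x$dim[1], x$dim[2])
    else x$data
  })
  params <- crbm_params(pr$R, pr$Sw, pr$Tw, pr$a, pr$b, pr$c, pr$d)
  cfg <- do.call(train_config, obj$config[c("hidden_units", "learning_rate",
                                            "epochs", "cd_k", "activation",
                                            "seed")])
  list(params = params, config = cfg,
       trace = as.data.frame(obj$trace, stringsAsFactors = FALSE))
}
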