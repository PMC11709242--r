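# Shared fixtures: tiny random models and an independent enumeration oracle.

rand_crbm <- function(nv = 2, ns = 1, np = 1, f = 2, sd = 0.5, seed = 1) {
  set.seed(seed)
  crbm_params(R = matrix(rnorm(nv * f, 0, sd), nv),
              Sw = matrix(rnorm(ns * f, 0, sd), ns),
              Tw = matrix(rnorm(np * f, 0, sd), np),
              a = rnorm(f, 0, sd), b = rnorm(nv, 0, sd),
              c = rnorm(ns, 0, sd), d = rnorm(np, 0, sd))
}

# Independent brute-force oracle: explicit per-configuration energy sums,
# no shared code with exact_distribution (scalar loops only).
enum_oracle <- function(p) {
  nv <- nrow(p$R); ns <- nrow(p$Sw); np <- nrow(p$Tw); f <- ncol(p$R)
  n <- nv + ns + np + f
  cfgs <- as.matrix(expand.grid(rep(list(0:1), n)))
  w <- numeric(nrow(cfgs))
  for (r in seq_len(nrow(cfgs))) {
    v <- cfgs[r, 1:nv]
    s <- cfgs[r, nv + seq_len(ns)]
    pp <- cfgs[r, nv + ns + seq_len(np)]
    h <- cfgs[r, nv + ns + np + seq_len(f)]
    e <- 0
    for (i in seq_len(nv)) e <- e - p$b[i] * v[i]
    for (i in seq_len(ns)) e <- e - p$c[i] * s[i]
    for (i in seq_len(np)) e <- e - p$d[i] * pp[i]
    for (j in seq_len(f)) e <- e - p$a[j] * h[j]
    for (i in seq_len(nv)) for (j in seq_len(f)) e <- e - v[i] * p$R[i, j] * h[j]
    for (i in seq_len(ns)) for (j in seq_len(f)) e <- e - s[i] * p$Sw[i, j] * h[j]
    for (i in seq_len(np)) for (j in seq_len(f)) e <- e - pp[i] * p$Tw[i, j] * h[j]
    w[r] <- exp(-e)
  }
  list(cfgs = cfgs, prob = w / sum(w))
}

# Conditional P(H_j = 1 | V = v, S = s, P = p) from an exact_distribution.
enum_hidden_conditional <- function(ed, v, s, p, j) {
  sel <- apply(ed$V, 1, function(r) all(r == v)) &
    apply(ed$S, 1, function(r) all(r == s)) &
    apply(ed$P, 1, function(r) all(r == p))
  sum(ed$prob[sel & ed$H[, j] == 1]) / sum(ed$prob[sel])
}

enum_visible_conditional <- function(ed, h, layer, i) {
  sel <- apply(ed$H, 1, function(r) all(r == h))
  sum(ed$prob[sel & ed[[layer]][, i] == 1]) / sum(ed$prob[sel])
}

tiny_ratings <- function(vals, obs = NULL) {
  vals <- as.matrix(vals)
  if (is.null(obs)) obs <- matrix(TRUE, nrow(vals), ncol(vals))
  ratings_matrix(vals * obs, obs,
                 paste0("u", seq_len(nrow(vals))),
                 paste0("f", seq_len(ncol(vals))))
}

# Small food table with controllable prices / nutrient coverage.
tiny_foods <- function(n, prices = rep(5, n), nutrients = NULL) {
  ids <- sprintf("f%03d", seq_len(n))
  if (is.null(nutrients))
    nutrients <- matrix(1, n, 2, dimnames = list(ids, c("Iron", "Protein")))
  structure(data.frame(food_id = ids, name = paste("Food", seq_len(n)),
                       price = prices, stringsAsFactors = FALSE),
            nutrients = nutrients,
            nutrient_units = stats::setNames(rep("mg", ncol(nutrients)),
                                             colnames(nutrients)),
            class = c("food_table", "data.frame"))
}
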