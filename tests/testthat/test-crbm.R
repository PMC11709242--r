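test_that("activation functions behave at their defining points", {
  expect_equal(sigmoid(0), 0.5)
  x <- c(-7.3, -0.1, 0, 2.4, 31)
  expect_equal(sigmoid(x), 1 - sigmoid(-x))
  expect_lt(sigmoid(-25), 1e-9)       # saturates, no underflow error
  expect_identical(relu(c(-3, 0, 2.5)), c(0, 0, 2.5))
})

test_that("energy matches the term-by-term hand evaluation", {
  # 1 visible / 0 similarity / 0 popularity / 1 hidden unit
  p <- crbm_params(R = matrix(1, 1, 1),
                   Sw = matrix(numeric(0), 0, 1),
                   Tw = matrix(numeric(0), 0, 1),
                   a = -0.2, b = 0.5, c = numeric(0), d = numeric(0))
  expect_equal(crbm_energy(1, numeric(0), numeric(0), 1, p),
               -0.5 + 0.2 - 1)       # = -1.3
  expect_equal(crbm_energy(0, numeric(0), numeric(0), 0, p), 0)
  p0 <- rand_crbm(2, 1, 1, 2, sd = 0)        # all parameters zero
  expect_equal(crbm_energy(c(1, 0), 1, 1, c(0, 1), p0), 0)
  expect_error(crbm_energy(c(1, 0, 1), 1, 1, c(0, 1), p0), "mismatch")
})

test_that("exact distribution normalizes and matches a brute-force oracle", {
  p <- rand_crbm(2, 1, 1, 2, sd = 0.8, seed = 7)
  ed <- exact_distribution(p)
  expect_equal(sum(ed$prob), 1, tolerance = 1e-12)
  oracle <- enum_oracle(p)
  expect_equal(ed$prob, oracle$prob, tolerance = 1e-12)
  expect_error(exact_distribution(rand_crbm(8, 4, 4, 8)), "too large")
})

test_that("a single pairwise weight of ln 2 doubles the (1,1) probability", {
  p <- crbm_params(R = matrix(log(2), 1, 1),
                   Sw = matrix(numeric(0), 0, 1),
                   Tw = matrix(numeric(0), 0, 1),
                   a = 0, b = 0, c = numeric(0), d = numeric(0))
  ed <- exact_distribution(p)
  p11 <- ed$prob[ed$V[, 1] == 1 & ed$H[, 1] == 1]
  p00 <- ed$prob[ed$V[, 1] == 0 & ed$H[, 1] == 0]
  expect_equal(p11 / p00, 2, tolerance = 1e-12)
})

test_that("conditionals equal enumeration conditionals on a 6-unit model", {
  p <- rand_crbm(2, 1, 1, 2, sd = 0.6, seed = 3)
  ed <- exact_distribution(p)
  for (v1 in 0:1) for (v2 in 0:1) for (s in 0:1) for (pp in 0:1) {
    hc <- hidden_conditional(p, c(v1, v2), s, pp)
    for (j in 1:2)
      expect_equal(hc[j], enum_hidden_conditional(ed, c(v1, v2), s, pp, j),
                   tolerance = 1e-10)
  }
  for (h1 in 0:1) for (h2 in 0:1) {
    rc <- reconstruct_conditionals(p, c(h1, h2))
    expect_equal(rc$V[1], enum_visible_conditional(ed, c(h1, h2), "V", 1),
                 tolerance = 1e-10)
    expect_equal(rc$S[1], enum_visible_conditional(ed, c(h1, h2), "S", 1),
                 tolerance = 1e-10)
    expect_equal(rc$P[1], enum_visible_conditional(ed, c(h1, h2), "P", 1),
                 tolerance = 1e-10)
  }
})

test_that("zero parameters give 0.5 everywhere; bias shifts are monotone", {
  p0 <- rand_crbm(3, 2, 2, 2, sd = 0)
  expect_equal(hidden_conditional(p0, c(1, 0, 1), c(1, 0), c(0, 1)),
               rep(0.5, 2))
  rc <- reconstruct_conditionals(p0, c(1, 0))
  expect_equal(unname(unlist(rc)), rep(0.5, 7))
  p1 <- p0; p1$a[1] <- 1
  expect_gt(hidden_conditional(p1, c(1, 0, 1), c(1, 0), c(0, 1))[1],
            hidden_conditional(p0, c(1, 0, 1), c(1, 0), c(0, 1))[1])
  # V reconstruction is independent of the context biases c, d
  p2 <- rand_crbm(2, 1, 1, 2, seed = 5)
  p3 <- p2; p3$c <- p3$c + 9; p3$d <- p3$d - 9
  expect_identical(reconstruct_conditionals(p2, c(1, 0))$V,
                   reconstruct_conditionals(p3, c(1, 0))$V)
})

test_that("gibbs_chain respects clamps and is seed-reproducible", {
  p <- rand_crbm(2, 1, 1, 2, seed = 2)
  st <- list(V = c(1, 0), S = 1, P = 0, H = c(0, 1))
  out <- gibbs_chain(st, p, steps = 5, clamp = c("V", "S", "P", "H"))
  expect_identical(out, st)
  set.seed(10); a <- gibbs_chain(st, p, steps = 20)
  set.seed(10); b <- gibbs_chain(st, p, steps = 20)
  expect_identical(a, b)
  # clamped layers survive an unclamped run of the others
  set.seed(3)
  out2 <- gibbs_chain(st, p, steps = 10, clamp = c("S", "P"))
  expect_identical(out2$S, st$S)
  expect_identical(out2$P, st$P)
})

test_that("zero-parameter chain has 0.5 marginals within Monte-Carlo error", {
  p0 <- rand_crbm(2, 1, 1, 2, sd = 0)
  set.seed(21)
  run <- gibbs_chain(list(V = c(0, 0), S = 0, P = 0, H = c(0, 0)), p0,
                     steps = 4000, record = TRUE)
  means <- colMeans(run$trace)
  se3 <- 3 * sqrt(0.25 / 4000)
  expect_true(all(abs(means - 0.5) < se3))
})

test_that("cd_update reproduces a hand-simulated CD-1 pass", {
  p <- rand_crbm(3, 2, 2, 2, sd = 0.4, seed = 6)
  v <- c(1, 0, 1); s <- c(0.5, 1); pp <- c(0.25, 0)
  obs <- c(TRUE, TRUE, FALSE)        # third item unobserved
  v <- v * obs
  cfg <- train_config(hidden_units = 2, learning_rate = 0.1, cd_k = 1,
                      seed = 1)
  set.seed(33)
  d <- cd_update(p, v, s, pp, obs, cfg)
  # replay the same draws step by step
  set.seed(33)
  hd <- sigmoid(p$a + as.numeric(v %*% p$R + s %*% p$Sw + pp %*% p$Tw))
  hs <- (runif(2) < hd) * 1
  vp <- sigmoid(p$b + as.numeric(p$R %*% hs))
  vn <- (runif(3) < vp) * obs
  hn <- sigmoid(p$a + as.numeric(vn %*% p$R + s %*% p$Sw + pp %*% p$Tw))
  expect_equal(d$R, 0.1 * (outer(v, hd) - outer(vn, hn)), tolerance = 1e-12)
  expect_equal(d$Sw, 0.1 * outer(s, hd - hn), tolerance = 1e-12)
  expect_equal(d$Tw, 0.1 * outer(pp, hd - hn), tolerance = 1e-12)
  expect_equal(d$a, 0.1 * (hd - hn), tolerance = 1e-12)
  expect_equal(d$b, 0.1 * (v - vn), tolerance = 1e-12)
  expect_equal(d$c, c(0, 0))
  expect_equal(d$d, c(0, 0))
  # unobserved item contributes to no delta
  expect_equal(unname(d$b[3]), 0)
  expect_error(cd_update(p, v, s, pp, obs,
                         structure(list(learning_rate = 0), class = "train_config")),
               "positive")
})

test_that("identical data and reconstruction give zero deltas", {
  # with saturating weights the reconstruction deterministically equals the
  # data, so both phases match and every delta vanishes
  p <- crbm_params(R = matrix(50, 1, 1), Sw = matrix(0, 1, 1),
                   Tw = matrix(0, 1, 1), a = -25, b = -25, c = 0, d = 0)
  cfg <- train_config(hidden_units = 1, learning_rate = 0.1, seed = 1)
  set.seed(2)
  d <- cd_update(p, v = 1, s = 0, p = 0, observed = TRUE, cfg)
  expect_equal(max(abs(unlist(d))), 0, tolerance = 1e-9)
})

test_that("training memorizes a noiseless one-group dataset", {
  gen <- generate_ratings(ratings_gen_spec(15, 12, 1, 0.6, 0, seed = 5))
  ctx <- context_scores(gen$ratings, gen$groups)
  cfg <- train_config(hidden_units = 20, learning_rate = 0.05, epochs = 50,
                      seed = 5)
  m <- crbm_train(gen$ratings, ctx, cfg)
  expect_equal(nrow(m$trace), 50)
  expect_lt(m$trace$train_rmse[50], 0.2)
  # zero epochs: parameters identical to the initialization
  m0 <- crbm_train(gen$ratings, ctx,
                   train_config(20, 0.05, epochs = 0, seed = 5))
  vobs <- gen$ratings$values * gen$ratings$observed
  means <- colSums(vobs) / colSums(gen$ratings$observed)
  expect_equal(m0$params, init_crbm(12, 12, 12, 20, visible_means = means,
                                    seed = 5))
  expect_equal(nrow(m0$trace), 0)
})

test_that("training is deterministic given the seed", {
  gen <- generate_ratings(ratings_gen_spec(10, 8, 2, 0.6, 0.1, seed = 2))
  ctx <- context_scores(gen$ratings, gen$groups)
  cfg <- train_config(5, 0.05, 10, seed = 9)
  m1 <- crbm_train(gen$ratings, ctx, cfg)
  m2 <- crbm_train(gen$ratings, ctx, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$trace, m2$trace)
})

test_that("prediction follows the mean-field sigmoid arithmetic", {
  p0 <- rand_crbm(2, 2, 2, 2, sd = 0)
  expect_equal(unname(predict_ratings(p0, c(1, 0), c(0, 0), c(0, 0), 1:2)),
               c(0.5, 0.5))
  p <- rand_crbm(2, 2, 2, 2, sd = 0.7, seed = 11)
  v <- c(1, 0); s <- c(0.3, 0.6); pp <- c(0.2, 0.9)
  hbar <- sigmoid(p$a + as.numeric(v %*% p$R + s %*% p$Sw + pp %*% p$Tw))
  manual <- sigmoid(p$b[2] + sum(p$R[2, ] * hbar))
  expect_equal(unname(predict_ratings(p, v, s, pp, 2)), manual,
               tolerance = 1e-12)
  expect_error(predict_ratings(p, v, s, pp, 5), "out of range")
  expect_warning(predict_ratings(p, v, s, pp, 1, observed = c(TRUE, FALSE)),
                 "already observed")
})

test_that("an overfit model predicts its user's liked items above 0.9", {
  rm <- tiny_ratings(matrix(c(1, 1, 0, 0, 1, 0, 1, 0), 1, 8))
  ctx <- context_scores(rm, 1)
  m <- crbm_train(rm, ctx, train_config(10, 0.05, 200, seed = 4))
  pred <- predict_matrix(m$params, rm, ctx)
  expect_true(all(pred[1, rm$values[1, ] == 1] > 0.9))
  expect_true(all(pred[1, rm$values[1, ] == 0] < 0.1))
})

test_that("checkpoints round-trip through JSON", {
  gen <- generate_ratings(ratings_gen_spec(8, 6, 2, 0.7, 0, seed = 1))
  ctx <- context_scores(gen$ratings, gen$groups)
  m <- crbm_train(gen$ratings, ctx, train_config(4, 0.05, 3, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  save_crbm(m, path)
  m2 <- load_crbm(path)
  expect_equal(m2$params, m$params)
  expect_equal(m2$trace$train_rmse, m$trace$train_rmse)
  expect_equal(m2$config$hidden_units, m$config$hidden_units)
})

test_that("train_config validates its window", {
  expect_error(train_config(hidden_units = 0), "hidden_units")
  expect_error(train_config(hidden_units = 300), "hidden_units")
  expect_error(train_config(learning_rate = -1), "positive")
  expect_error(train_config(cd_k = 0), "cd_k")
})
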