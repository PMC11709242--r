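test_that("greedy grouping follows the Jaccard rule", {
  # all users share one item set -> a single group
  rm <- tiny_ratings(matrix(1, 4, 3))
  g <- build_groups(rm, 0.2)
  expect_length(g, 1)
  expect_setequal(g[[1]]$member_ids, rm$user_ids)

  # pairwise-disjoint item sets -> one singleton group per user
  obs <- diag(3) == 1
  rm2 <- tiny_ratings(matrix(1, 3, 3), obs)
  g2 <- build_groups(rm2, 0.2)
  expect_length(g2, 3)
  expect_true(all(lengths(lapply(g2, `[[`, "member_ids")) == 1))

  # A-B overlap 0.8, A-C and B-C below threshold -> {A,B}, {C}
  obs3 <- matrix(FALSE, 3, 12)
  obs3[1, 1:9] <- TRUE                  # A: items 1..9
  obs3[2, c(1:8, 10)] <- TRUE           # B: 8 shared of 10 union -> 0.8
  obs3[3, c(1, 11, 12)] <- TRUE         # C: barely overlaps either
  rm3 <- tiny_ratings(matrix(1, 3, 12), obs3)
  g3 <- build_groups(rm3, 0.5)
  expect_length(g3, 2)
  expect_setequal(g3[[1]]$member_ids, c("u1", "u2"))
  expect_setequal(g3[[2]]$member_ids, "u3")
  # item subset is the union of members' items
  expect_setequal(g3[[1]]$item_subset, paste0("f", 1:10))
})

test_that("group structures partition users deterministically", {
  gen <- generate_ratings(ratings_gen_spec(40, 25, 4, 0.4, 0.1, seed = 6))
  g <- build_groups(gen$ratings, 0.2)
  members <- unlist(lapply(g, `[[`, "member_ids"))
  expect_setequal(members, gen$ratings$user_ids)
  expect_equal(anyDuplicated(members), 0)
  g2 <- build_groups(gen$ratings, 0.2)
  expect_identical(g, g2)
})

test_that("a single group covering all items equals the plain trainer", {
  gen <- generate_ratings(ratings_gen_spec(12, 10, 1, 0.8, 0.05, seed = 3))
  ctx <- context_scores(gen$ratings, gen$groups)
  cfg <- train_config(6, 0.05, 8, seed = 3)
  rated <- which(colSums(gen$ratings$observed) > 0)
  g <- structure(list(member_ids = gen$ratings$user_ids,
                      item_subset = gen$ratings$item_ids[rated],
                      index_map = rated), class = "user_group")
  mg <- train_groups(gen$ratings, list(g), cfg, context = ctx)
  mp <- crbm_train(gen$ratings, ctx, cfg)
  expect_identical(mg$params, mp$params)
  expect_identical(mg$trace, mp$trace)
})

test_that("updates are local to each group's item subset", {
  # two groups over disjoint item blocks
  obs <- matrix(FALSE, 6, 10)
  obs[1:3, 1:5] <- TRUE
  obs[4:6, 6:10] <- TRUE
  set.seed(8)
  rm <- tiny_ratings(matrix(rbinom(60, 1, 0.5), 6, 10), obs)
  groups <- build_groups(rm, 0.2)
  expect_length(groups, 2)
  cfg <- train_config(4, 0.05, 1, seed = 2)
  ctx <- context_scores(rm, groups)
  m <- train_groups(rm, groups, cfg, context = ctx)
  init <- init_crbm(10, 10, 10, 4,
                    visible_means = colSums(rm$values * rm$observed) /
                      pmax(colSums(rm$observed), 1), seed = 2)
  sub1 <- groups[[1]]$index_map
  sub2 <- groups[[2]]$index_map
  # each group's R rows moved; rows outside both subsets would be untouched
  expect_false(isTRUE(all.equal(m$params$R[sub1, ], init$R[sub1, ])))
  expect_false(isTRUE(all.equal(m$params$R[sub2, ], init$R[sub2, ])))
  # group 1 trains first, so after one epoch its rows match a solo run of
  # group 1 alone (same seed, same draw sequence)
  solo <- train_groups(rm, groups[1], cfg, context = ctx)
  expect_equal(m$params$R[sub1, ], solo$params$R[sub1, ], tolerance = 1e-12)
  expect_equal(m$params$Sw[sub1, ], solo$params$Sw[sub1, ], tolerance = 1e-12)
  expect_equal(m$params$b[sub1], solo$params$b[sub1], tolerance = 1e-12)
})

test_that("items rated by no user keep their initial parameters", {
  obs <- matrix(FALSE, 4, 6)
  obs[, 1:4] <- TRUE                    # items 5 and 6 never rated
  set.seed(12)
  rm <- tiny_ratings(matrix(rbinom(24, 1, 0.5), 4, 6), obs)
  groups <- build_groups(rm, 0.2)
  cfg <- train_config(3, 0.05, 5, seed = 7)
  m <- train_groups(rm, groups, cfg)
  init <- init_crbm(6, 6, 6, 3,
                    visible_means = ifelse(colSums(obs) > 0,
                                           colSums(rm$values * obs) /
                                             pmax(colSums(obs), 1), NA),
                    seed = 7)
  expect_identical(m$params$R[5:6, ], init$R[5:6, ])
  expect_identical(m$params$b[5:6], init$b[5:6])
})

test_that("the expected per-case update does not depend on group size", {
  # the first per-case step of an epoch is identical whether the user's
  # group holds n members or 2n (duplicated) members
  set.seed(20)
  rm <- tiny_ratings(matrix(rbinom(12, 1, 0.5), 3, 4))
  dup_vals <- rbind(rm$values, rm$values)
  dup <- ratings_matrix(dup_vals, matrix(TRUE, 6, 4),
                        paste0("u", 1:6), rm$item_ids)
  cfg <- train_config(3, 0.05, 1, seed = 5)
  g1 <- build_groups(rm, 0.1)
  m1 <- train_groups(rm, g1, cfg)
  # after one epoch over n members the parameters moved by sum of n
  # per-case deltas; the duplicated run moves by 2n such deltas of the
  # same expected size, so the per-member displacement agrees closely
  init <- init_crbm(4, 4, 4, 3,
                    visible_means = colMeans(rm$values), seed = 5)
  disp1 <- (m1$params$R - init$R) / 3
  g2 <- build_groups(dup, 0.1)
  init2 <- init_crbm(4, 4, 4, 3, visible_means = colMeans(dup$values),
                     seed = 5)
  m2 <- train_groups(dup, g2, cfg)
  disp2 <- (m2$params$R - init2$R) / 6
  expect_equal(dim(disp1), dim(disp2))
  expect_lt(mean(abs(disp1 - disp2)), 0.05)   # Monte-Carlo tolerance
})

test_that("warm starts resume from a checkpoint's parameters", {
  gen <- generate_ratings(ratings_gen_spec(10, 8, 2, 0.6, 0.05, seed = 4))
  groups <- build_groups(gen$ratings, 0.2)
  cfg <- train_config(4, 0.05, 4, seed = 4)
  m <- train_groups(gen$ratings, groups, cfg)
  m2 <- train_groups(gen$ratings, groups,
                     train_config(4, 0.05, 0, seed = 4), params = m$params)
  expect_identical(m2$params, m$params)
})
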