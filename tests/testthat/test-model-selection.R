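test_that("fold plans are balanced, disjoint, exhaustive, and seeded", {
  ids <- sprintf("i%03d", 1:100)
  doms <- rep(c("animate", "inanimate"), each = 50)
  plan <- make_fold_plan(ids, doms, k_outer = 10, seed = 1)
  expect_equal(sort(unique(plan$assignment)), 1:10)
  for (f in 1:10) {
    expect_equal(sum(plan$assignment == f & doms == "animate"), 5)
    expect_equal(sum(plan$assignment == f & doms == "inanimate"), 5)
  }
  expect_identical(plan$assignment,
                   make_fold_plan(ids, doms, 10, seed = 1)$assignment)
  plan2 <- make_fold_plan(ids, doms, 10, seed = 2)
  expect_false(identical(plan$assignment, plan2$assignment))
  expect_error(make_fold_plan(ids[1:99], doms[1:99], 10), "cannot balance")
})

test_that("inner_loop_score behaves at the limits", {
  set.seed(60)
  X <- matrix(rnorm(40 * 6), 40, 6)
  beta_star <- matrix(rnorm(18), 6, 3)
  U <- X %*% beta_star
  inner <- rep(1:4, each = 10)
  # noiseless planted system with a tiny penalty: near-zero error
  s0 <- inner_loop_score(X, U, inner, "growl",
                         list(alpha = 1e-8, lam = 0.1, omega = 0.1))
  expect_lt(s0, 0.05)
  # huge alpha: zero model, error equals the norm of the centered holdout
  s_inf <- inner_loop_score(X, U, inner, "growl",
                            list(alpha = 1e6, lam = 1, omega = 1))
  expect_gt(s_inf, s0)
  expect_gte(s0, 0)
})

test_that("hyperband search degenerates gracefully and is deterministic", {
  set.seed(61)
  X <- matrix(rnorm(40 * 6), 40, 6)
  U <- X[, 1:2] %*% matrix(rnorm(6), 2, 3) + matrix(rnorm(120, sd = 0.1), 40, 3)
  inner <- rep(1:4, each = 10)
  # single grid candidate is returned unchanged
  cfg <- list(alpha = 0.02, lam = 0.1, omega = 0.1)
  got <- hyperband_search(X, U, inner, "growl", search = "grid", grid = list(cfg))
  expect_equal(got$best, cfg)
  # two grid candidates: the lower-scoring one wins
  bad <- list(alpha = 1e5, lam = 1, omega = 1)
  got2 <- hyperband_search(X, U, inner, "growl", search = "grid",
                           grid = list(bad, cfg))
  expect_equal(got2$best, cfg)
  expect_error(hyperband_search(X, U, inner, "growl", search = "grid",
                                grid = list()), "empty")
  # fixed seed -> identical selection
  a <- hyperband_search(X, U, inner, "growl", n_configs = 6, max_budget = 300,
                        seed = 7)
  b <- hyperband_search(X, U, inner, "growl", n_configs = 6, max_budget = 300,
                        seed = 7)
  expect_identical(a$best, b$best)
  expect_error(hyperband_search(X, U, inner, "growl", n_configs = 0), "bracket")
})

test_that("nested CV predicts every item out of fold", {
  emb <- fixture_embedding()
  X <- make_condition_dataset(emb, signal_condition("full"), 0.5, seed = 62)
  plan <- make_fold_plan(emb$item_ids, emb$domains, 10, seed = 63)
  cvp <- nested_cv_decode(X, emb$coords, plan, family = "none")
  expect_false(anyNA(cvp$predicted))
  expect_equal(dim(cvp$predicted), dim(emb$coords))
  # planted low-noise data: assembled holdout predictions track the target
  for (k in 1:3) expect_gt(cor(cvp$predicted[, k], emb$coords[, k]), 0.9)
})

test_that("holdout targets cannot leak into holdout predictions", {
  emb <- fixture_small_embedding()
  set.seed(64)
  X <- matrix(rnorm(20 * 8), 20, 8)
  plan <- make_fold_plan(emb$item_ids, emb$domains, 5, seed = 65)
  U <- emb$coords
  cvp1 <- nested_cv_decode(X, U, plan, family = "growl",
                           search = list(fixed = list(alpha = 0.05, lam = 0.1,
                                                      omega = 0.1)))
  hold <- plan$assignment == 1
  U2 <- U
  U2[hold, ] <- matrix(rnorm(sum(hold) * 3) * 100, ncol = 3)
  cvp2 <- nested_cv_decode(X, U2, plan, family = "growl",
                           search = list(fixed = list(alpha = 0.05, lam = 0.1,
                                                      omega = 0.1)))
  expect_equal(cvp1$predicted[hold, ], cvp2$predicted[hold, ], tolerance = 1e-10)
})

test_that("nested CV is deterministic given data, seed and config", {
  emb <- fixture_small_embedding()
  set.seed(66)
  X <- emb$coords %*% matrix(rnorm(24), 3, 8) + matrix(rnorm(160, sd = 0.4), 20, 8)
  plan <- make_fold_plan(emb$item_ids, emb$domains, 5, seed = 67)
  run <- function() nested_cv_decode(
    X, emb$coords, plan, family = "growl",
    search = list(n_configs = 4, max_budget = 300), seed = 11)
  expect_identical(run()$predicted, run()$predicted)
})

test_that("shuffled targets yield null-centered holdout correlations", {
  emb <- fixture_embedding()
  X <- make_condition_dataset(emb, signal_condition("full"), 0.5, seed = 68)
  plan <- make_fold_plan(emb$item_ids, emb$domains, 10, seed = 69)
  set.seed(70)
  rs <- replicate(20, {
    U <- emb$coords[sample(100), ]
    cvp <- nested_cv_decode(X, U, plan, family = "none")
    mean(diag(cor(cvp$predicted, U)))
  })
  # cross-validated correlation is negatively biased under the null
  expect_lt(mean(rs), 0.02)
})
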