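test_that("signal conditions validate their structure", {
  cond <- signal_condition("full", n_features = 24)
  expect_equal(cond$n_signal, 12L)
  expect_equal(cond$dims_encoded, 1:3)
  expect_error(signal_condition("full", n_features = 20, n_signal = 10),
               "divide evenly")
  expect_error(signal_condition("binary", n_features = 24, n_signal = 30),
               "exceed")
  expect_error(noise_spec(levels = c(0.5, 0.2)), "strictly increasing")
  expect_error(noise_spec(reps = 0), "reps")
})

test_that("synthetic feature norms satisfy the feature-norm invariants", {
  norms <- fixture_norms()
  expect_true(all(norms$values %in% 0:1))
  expect_true(all(rowSums(norms$values) > 0))
  expect_equal(sum(norms$domains == "animate"), 50)
  expect_equal(sum(norms$domains == "inanimate"), 50)
  # the embedding target structure: dominant graded first component
  emb <- fixture_embedding()
  expect_gt(emb$variance_explained[1], 5 * emb$variance_explained[2])
  an <- norms$domains == "animate"
  expect_gt(abs(cor(emb$coords[, 1], as.numeric(an))), 0.8)
  # components carry within-domain variance in both domains
  expect_gt(var(emb$coords[an, 1]), 0)
  expect_gt(var(emb$coords[!an, 1]), 0)
})

test_that("binary condition plants an exact domain code at zero noise", {
  emb <- fixture_embedding()
  X <- make_condition_dataset(emb, signal_condition("binary"), 0, seed = 5)
  sig <- attr(X, "signal_columns")
  expect_length(sig, 12)
  an <- emb$domains == "animate"
  for (j in sig) {
    expect_equal(length(unique(X[an, j])), 1)
    expect_equal(length(unique(X[!an, j])), 1)
    expect_equal(unname(X[an, j][1]), unname(-X[!an, j][1]))
    expect_true(all(X[, j] %in% c(-1, 1)))
  }
})

test_that("oneD conditions plant exact copies of one component", {
  emb <- fixture_embedding()
  for (k in 1:3) {
    X <- make_condition_dataset(emb, signal_condition(paste0("oneD-", k)), 0,
                                seed = 6)
    for (j in attr(X, "signal_columns")) {
      expect_equal(abs(cor(X[, j], emb$coords[, k])), 1, tolerance = 1e-12)
    }
  }
})

test_that("full condition dedicates equal feature counts per component", {
  emb <- fixture_embedding()
  X <- make_condition_dataset(emb, signal_condition("full", n_features = 24), 0,
                              seed = 7)
  sig <- attr(X, "signal_columns")
  expect_length(sig, 12)
  hits <- sapply(1:3, function(k) {
    sum(vapply(sig, function(j) {
      isTRUE(all.equal(abs(cor(X[, j], emb$coords[, k])), 1, tolerance = 1e-8))
    }, logical(1)))
  })
  expect_equal(hits, c(4, 4, 4))
})

test_that("generators are pure functions of their seed", {
  emb <- fixture_small_embedding()
  a <- make_condition_dataset(emb, signal_condition("full"), 1.2, seed = 42)
  b <- make_condition_dataset(emb, signal_condition("full"), 1.2, seed = 42)
  expect_identical(a, b)
  expect_false(identical(
    a, make_condition_dataset(emb, signal_condition("full"), 1.2, seed = 43)))
  e1 <- make_synthetic_ephys(fixture_embedding(), snr = 4, seed = 9)
  e2 <- make_synthetic_ephys(fixture_embedding(), snr = 4, seed = 9)
  expect_identical(e1$X, e2$X)
})

test_that("sweep_conditions enumerates the full design reproducibly", {
  emb <- fixture_small_embedding()
  noise <- noise_spec(levels = c(0, 1, 2), reps = 2, seed = 10)
  conds <- standard_conditions()[c("binary", "full")]
  sw <- sweep_conditions(emb, conds, noise)
  expect_length(sw, 2 * 3 * 2)
  sw2 <- sweep_conditions(emb, conds, noise)
  expect_identical(sw, sw2)
  # noiseless fixture mode
  sw0 <- sweep_conditions(emb, conds["binary"], noise_spec(levels = 0, reps = 1))
  expect_length(sw0, 1)
})

test_that("synthetic ephys plants signal only inside the latency band", {
  emb <- fixture_embedding()
  eph <- make_synthetic_ephys(emb, snr = 100, seed = 12)
  expect_equal(dim(eph$X), c(100, 2000))
  support <- which(colSums(abs(eph$ground_truth_mixing)) > 0)
  expect_length(support, 40)
  tms <- eph$column_map$time_ms[support]
  expect_true(all(tms >= 150 & tms < 700))
  # columns outside the window are uncorrelated with every embedding dim
  outside <- which(eph$column_map$time_ms < 150 | eph$column_map$time_ms >= 700)
  cors <- abs(cor(eph$X[, sample(outside, 200)], emb$coords))
  expect_lt(mean(cors), 0.12)  # null |r| has mean ~0.08 at n = 100
  expect_lt(max(cors), 0.5)
  # near-duplicate groups correlate pairwise before noise dominates
  for (g in eph$group_structure[1:3]) {
    cg <- cor(emb$coords[, 1:3] %*% eph$ground_truth_mixing[, g, drop = FALSE])
    expect_true(all(cg[lower.tri(cg)] >= 0.9))
  }
})

test_that("noiseless ephys is exactly decodable from the signal columns", {
  emb <- fixture_embedding()
  eph <- make_synthetic_ephys(emb, snr = 1e8, seed = 13)
  support <- which(colSums(abs(eph$ground_truth_mixing)) > 0)
  Z <- scale(emb$coords[, 1:3])
  train <- 1:80; test <- 81:100
  beta <- MASS::ginv(eph$X[train, support]) %*% Z[train, ]
  pred <- eph$X[test, support] %*% beta
  for (k in 1:3) expect_gt(cor(pred[, k], Z[test, k]), 0.99)
})

test_that("infeasible ephys requests error cleanly", {
  emb <- fixture_embedding()
  expect_error(make_synthetic_ephys(emb, n_signal_columns = 4000), "exceeds")
  expect_error(make_synthetic_ephys(emb, signal_window = c(150, 200),
                                    n_signal_columns = 400), "too narrow")
})
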