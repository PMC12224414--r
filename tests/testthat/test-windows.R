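test_that("boxcar downsampling averages within boxcars", {
  # constant signal is unchanged
  v <- array(5, c(2, 3, 1000))
  ds <- boxcar_downsample(trial_timeseries(v, 1000))
  expect_equal(dim(ds$voltages), c(2, 3, 100))
  expect_true(all(ds$voltages == 5))
  expect_equal(ds$sample_rate, 100)
  # a single boxcar of (0, ..., 0, 10) averages to 1
  v2 <- array(0, c(1, 1, 10))
  v2[1, 1, 10] <- 10
  ds2 <- boxcar_downsample(trial_timeseries(v2, 1000, epoch = c(0, 10)), to_hz = 100)
  expect_equal(as.numeric(ds2$voltages), 1)
  expect_error(boxcar_downsample(trial_timeseries(array(0, c(1, 1, 30)), 30,
                                                  epoch = c(0, 1000)),
                                 to_hz = 100),
               "integer multiple")
})

test_that("repetition averaging removes the repetition axis", {
  set.seed(90)
  rep1 <- array(rnorm(2 * 2 * 100), c(2, 2, 100))
  expect_equal(average_repetitions(list(rep1, rep1))$voltages, rep1)
  expect_true(all(average_repetitions(list(rep1, -rep1))$voltages == 0))
  reps4 <- array(rnorm(4 * 2 * 2 * 100), c(4, 2, 2, 100))
  out <- average_repetitions(reps4)
  expect_equal(dim(out$voltages), c(2, 2, 100))
  expect_equal(out$voltages, apply(reps4, 2:4, mean), ignore_attr = TRUE)
  expect_message(average_repetitions(list(rep1, NULL, rep1)), "missing dropped")
})

test_that("outlier censoring removes columns first, then rows", {
  set.seed(91)
  X <- matrix(rnorm(60 * 40), 60, 40)
  clean <- censor_outliers(X)
  expect_length(clean$removed_columns, 0)
  expect_length(clean$removed_rows, 0)
  # one wildly shifted column is censored; rows survive
  X2 <- X; X2[, 7] <- X2[, 7] + 100
  out <- censor_outliers(X2)
  expect_equal(out$removed_columns, 7)
  expect_length(out$removed_rows, 0)
  expect_equal(dim(out$X), c(60, 39))
})

test_that("censoring a bad column can rescue its row", {
  # one extreme cell inflates both its column's and its row's marginal
  # mean; removing the column first (and recomputing) leaves a clean row
  set.seed(92)
  X <- matrix(rnorm(50 * 30), 50, 30)
  X[3, 12] <- 400
  out <- censor_outliers(X)
  expect_true(12 %in% out$removed_columns)
  expect_false(3 %in% out$removed_rows)
  # row-first ordering on the same fixture would have removed row 3
  rm_first <- abs(rowMeans(X) - mean(X)) > 5 * sd(rowMeans(X))
  expect_true(rm_first[3])
})

test_that("window specs enumerate the published windows", {
  op <- window_spec("opening")
  expect_equal(nrow(op$windows), 11)
  expect_equal(op$windows[, "offset"] - op$windows[, "onset"],
               c(50, seq(100, 1000, by = 100)))
  expect_true(all(op$windows[, "onset"] == 0))
  mv <- window_spec("moving")
  expect_equal(nrow(mv$windows), 19)
  expect_equal(mv$windows[, "onset"], seq(0, 900, by = 50))
  expect_true(all(mv$windows[, "offset"] - mv$windows[, "onset"] == 100))
  fl <- window_spec("full")
  expect_equal(unname(fl$windows[1, ]), c(0, 1000))
})

test_that("slice_windows selects columns by time tag", {
  emb <- fixture_embedding()
  eph <- make_synthetic_ephys(emb, n_electrodes = 4, n_timepoints = 100,
                              n_signal_columns = 8, group_size = 2, seed = 93)
  mv <- slice_windows(eph$X, eph$column_map, window_spec("moving"))
  expect_length(mv, 19)
  sizes <- vapply(mv, function(w) ncol(w$X), integer(1))
  expect_true(all(sizes == sizes[1]))  # equal-sized moving windows
  op <- slice_windows(eph$X, eph$column_map, window_spec("opening"))
  expect_length(op, 11)
  expect_equal(ncol(op[[11]]$X), ncol(eph$X))
  fl <- slice_windows(eph$X, eph$column_map, window_spec("full"))
  expect_identical(fl[[1]]$X, eph$X)
  # all moving-window columns really lie inside their window
  w5 <- mv[[5]]
  expect_true(all(w5$column_map$time_ms >= w5$window["onset"] &
                    w5$column_map$time_ms < w5$window["offset"]))
})

test_that("evaluate_predictions reports per-dimension, per-subset r", {
  emb <- fixture_embedding()
  ev <- evaluate_predictions(emb$coords, emb)
  expect_equal(nrow(ev), 9)
  expect_equal(ev$r, rep(1, 9), tolerance = 1e-12)
  ev_neg <- evaluate_predictions(-emb$coords, emb)
  expect_equal(ev_neg$r, rep(-1, 9), tolerance = 1e-12)
})

test_that("domain-mean predictions show the binary-code signature", {
  emb <- fixture_embedding()
  an <- emb$domains == "animate"
  P <- emb$coords
  # replace within-domain structure by the domain mean + tiny jitter
  set.seed(94)
  for (k in 1:3) {
    P[an, k] <- mean(emb$coords[an, k]) + rnorm(sum(an), sd = 1e-6)
    P[!an, k] <- mean(emb$coords[!an, k]) + rnorm(sum(!an), sd = 1e-6)
  }
  ev <- evaluate_predictions(P, emb)
  r_all_d1 <- ev$r[ev$dimension == 1 & ev$subset == "all"]
  expect_gt(r_all_d1, 0.8)  # dim 1 tracks the domain split
  within <- ev$r[ev$subset != "all"]
  # within-domain correlations are jitter-driven noise around zero
  expect_true(all(abs(within) < 0.45))
  expect_lt(abs(mean(within)), 0.2)
})

test_that("reconstruction scoring is exact for the true embedding", {
  emb <- fixture_embedding()
  sc <- score_reconstruction(emb$coords, emb)
  expect_equal(nrow(sc), 9)
  expect_true(all(abs(sc$mean_r - 1) < 1e-10))
  # zero coordinates give undefined (missing) correlations
  sc0 <- score_reconstruction(matrix(0, 100, 3), emb)
  expect_true(all(is.na(sc0$mean_r)))
  # domain-mean-only predictions: the domain contrast dominates rows that
  # span both domains, while similarities restricted to one domain are
  # constant under a pure domain code, hence near-zero correlations
  an <- emb$domains == "animate"
  P <- emb$coords
  set.seed(95)
  for (k in 1:3) {
    P[an, k] <- mean(emb$coords[an, k]) + rnorm(sum(an), sd = 1e-6)
    P[!an, k] <- mean(emb$coords[!an, k]) + rnorm(sum(!an), sd = 1e-6)
  }
  scd <- score_reconstruction(P, emb)
  all_others <- scd$mean_r[scd$scope == "all_others" & scd$group == "all"]
  same <- scd$mean_r[scd$scope == "same_domain" & scd$group == "all"]
  other <- scd$mean_r[scd$scope == "other_domain" & scd$group == "all"]
  expect_gt(all_others, 0.6)
  expect_lt(abs(same), 0.45)
  expect_lt(abs(other), 0.45)
})

test_that("run_study aggregates a small synthetic cohort", {
  emb <- fixture_embedding()
  subjects <- lapply(1:2, function(s) {
    eph <- make_synthetic_ephys(emb, n_electrodes = 6, n_timepoints = 20,
                                n_signal_columns = 12, group_size = 2,
                                signal_window = c(150, 700), snr = 8,
                                seed = 100 + s)
    list(X = eph$X, column_map = eph$column_map)
  })
  spec <- window_spec("full")
  res <- run_study(subjects, emb, spec, family = "growl",
                   search = list(fixed = list(alpha = 0.02, lam = 0.05,
                                              omega = 0.05)),
                   n_perm_subject = 10, n_group = 500,
                   retune_permutations = FALSE, seed = 3)
  expect_s3_class(res, "rsl_study")
  expect_equal(nrow(res$table), 9)
  expect_true(all(res$table$p > 0 & res$table$p <= 1))
  expect_true(all(res$table$p_adj >= res$table$p - 1e-12))
  # the planted all-items first-dimension signal is recovered
  d1 <- res$table[res$table$dimension == 1 & res$table$subset == "all", ]
  expect_lt(d1$p, 0.1)
  expect_gt(d1$centered, 0.3)
  expect_error(run_study(subjects, emb,
                         structure(list(mode = "moving",
                                        windows = matrix(numeric(0), 0, 2),
                                        epoch = c(0, 1000)),
                                   class = "window_spec")),
               "empty window")
})
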