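# Neural-data preprocessing and temporal-window orchestration: boxcar
# downsampling, repetition averaging, outlier censoring, opening/moving
# window slicing, prediction evaluation, similarity-reconstruction scoring,
# and the multi-subject study driver.

#' Trial time-series container
#'
#' @param voltages items x electrodes x timepoints numeric array.
#' @param sample_rate sampling rate in Hz.
#' @param epoch `c(start, end)` in ms relative to stimulus onset (default
#'   `c(0, 1000)`).
#' @param repetitions_averaged whether repetitions were already averaged.
#' @return An object of class `trial_timeseries`.
#' @export
trial_timeseries <- function(voltages, sample_rate, epoch = c(0, 1000),
                             repetitions_averaged = TRUE) {
  if (length(dim(voltages)) != 3) {
    stop("voltages must be an items x electrodes x timepoints array", call. = FALSE)
  }
  expected <- (epoch[2] - epoch[1]) / 1000 * sample_rate
  if (dim(voltages)[3] != expected) {
    stop(sprintf("expected %d timepoints for a %d ms epoch at %g Hz, got %d",
                 as.integer(expected), epoch[2] - epoch[1], sample_rate,
                 dim(voltages)[3]), call. = FALSE)
  }
  structure(list(voltages = voltages, sample_rate = sample_rate, epoch = epoch,
                 repetitions_averaged = repetitions_averaged),
            class = "trial_timeseries")
}

#' Boxcar downsampling
#'
#' Averages measurements within contiguous boxcars (e.g. 1000 Hz to 100 Hz
#' uses 10 ms boxcars of 10 samples each).
#'
#' @param ts a `trial_timeseries`, or a 3-D voltages array.
#' @param from_hz,to_hz source and target rates; `from_hz` must be an
#'   integer multiple of `to_hz`.
#' @return A `trial_timeseries` at `to_hz`.
#' @export
boxcar_downsample <- function(ts, from_hz = NULL, to_hz = 100) {
  v <- if (inherits(ts, "trial_timeseries")) ts$voltages else ts
  if (inherits(ts, "trial_timeseries") && is.null(from_hz)) from_hz <- ts$sample_rate
  epoch <- if (inherits(ts, "trial_timeseries")) ts$epoch else c(0, dim(v)[3] / from_hz * 1000)
  if (from_hz %% to_hz != 0) {
    stop("from_hz must be an integer multiple of to_hz", call. = FALSE)
  }
  k <- from_hz / to_hz
  nt <- dim(v)[3]
  if (nt %% k != 0) stop("timepoint count is not divisible by the boxcar width", call. = FALSE)
  out_nt <- nt / k
  dim_in <- dim(v)
  # average over boxcars along the time axis
  arr <- array(v, c(dim_in[1] * dim_in[2], k, out_nt))
  m <- apply(arr, c(1, 3), mean)
  out <- array(m, c(dim_in[1], dim_in[2], out_nt))
  dimnames(out) <- list(dimnames(v)[[1]], dimnames(v)[[2]], NULL)
  trial_timeseries(out, sample_rate = to_hz, epoch = epoch)
}

#' Average voltages over stimulus repetitions
#'
#' @param reps list of items x electrodes x timepoints arrays (one per
#'   repetition) or a 4-D array with repetitions on the first axis. Missing
#'   repetitions (`NULL` entries) are dropped with a message.
#' @param sample_rate sampling rate of the input in Hz.
#' @param epoch epoch in ms.
#' @return A `trial_timeseries` with the repetition axis removed.
#' @export
average_repetitions <- function(reps, sample_rate = 100, epoch = c(0, 1000)) {
  if (is.array(reps) && length(dim(reps)) == 4) {
    reps <- lapply(seq_len(dim(reps)[1]), function(i) reps[i, , , , drop = TRUE])
  }
  keep <- !vapply(reps, is.null, logical(1))
  if (!all(keep)) {
    message(sprintf("averaging over %d of %d repetitions (missing dropped)",
                    sum(keep), length(reps)))
    reps <- reps[keep]
  }
  if (length(reps) == 0) stop("no repetitions to average", call. = FALSE)
  acc <- Reduce(`+`, reps) / length(reps)
  trial_timeseries(acc, sample_rate = sample_rate, epoch = epoch)
}

#' Flatten a trial time-series to a neural feature matrix
#'
#' Concatenates electrodes' time courses into one row vector per item and
#' records electrode/time provenance per column.
#'
#' @param ts a `trial_timeseries`.
#' @return List with `X` (items x (electrodes*timepoints)) and `column_map`
#'   (data.frame `electrode`, `time_ms`).
#' @export
flatten_timeseries <- function(ts) {
  stopifnot(inherits(ts, "trial_timeseries"))
  d <- dim(ts$voltages)
  n <- d[1]; ne <- d[2]; nt <- d[3]
  X <- matrix(aperm(ts$voltages, c(1, 3, 2)), nrow = n)  # time fastest within electrode
  step_ms <- 1000 / ts$sample_rate
  column_map <- data.frame(
    electrode = rep(seq_len(ne), each = nt),
    time_ms = ts$epoch[1] + rep((seq_len(nt) - 1) * step_ms, times = ne)
  )
  rownames(X) <- dimnames(ts$voltages)[[1]]
  list(X = X, column_map = column_map)
}

#' Censor extreme-outlier columns, then rows
#'
#' Removes feature columns whose marginal mean lies more than
#' `threshold_sd` standard deviations from the grand mean, then recomputes
#' the statistics on the remaining columns and removes items (rows) by the
#' same rule.
#'
#' @param X items x features matrix.
#' @param column_map optional column provenance, subset alongside `X`.
#' @param threshold_sd rejection threshold in SD units (default 5).
#' @return List with `X`, `column_map`, `removed_columns`, `removed_rows`.
#' @export
censor_outliers <- function(X, column_map = NULL, threshold_sd = 5) {
  if (threshold_sd <= 0) stop("threshold_sd must be positive", call. = FALSE)
  cm <- colMeans(X)
  bad_cols <- which(abs(cm - mean(X)) > threshold_sd * sd(cm))
  if (length(bad_cols) == ncol(X)) stop("all columns were censored", call. = FALSE)
  Xc <- if (length(bad_cols)) X[, -bad_cols, drop = FALSE] else X
  rm_ <- rowMeans(Xc)
  bad_rows <- which(abs(rm_ - mean(Xc)) > threshold_sd * sd(rm_))
  Xr <- if (length(bad_rows)) Xc[-bad_rows, , drop = FALSE] else Xc
  if (!is.null(column_map) && length(bad_cols)) {
    column_map <- column_map[-bad_cols, , drop = FALSE]
  }
  list(X = Xr, column_map = column_map,
       removed_columns = bad_cols, removed_rows = bad_rows)
}

#' Temporal window specification
#'
#' @param mode `"full"` (one window covering the epoch), `"opening"`
#'   (shared onset 0, widths 50 then 100..1000 ms by 100), or `"moving"`
#'   (fixed `width` windows advancing by `step`; the last onset is the
#'   final full window inside the epoch).
#' @param width moving-window width in ms (default 100).
#' @param step moving-window step in ms (default 50).
#' @param epoch `c(start, end)` in ms (default `c(0, 1000)`).
#' @return An object of class `window_spec` with a `windows` matrix of
#'   (onset, offset) rows.
#' @export
window_spec <- function(mode = c("full", "opening", "moving"), width = 100,
                        step = 50, epoch = c(0, 1000)) {
  mode <- match.arg(mode)
  windows <- switch(mode,
    full = matrix(epoch, 1, 2),
    opening = cbind(epoch[1], epoch[1] + c(50, seq(100, epoch[2] - epoch[1], by = 100))),
    moving = {
      onsets <- seq(epoch[1], epoch[2] - width, by = step)
      cbind(onsets, onsets + width)
    }
  )
  colnames(windows) <- c("onset", "offset")
  rownames(windows) <- NULL
  if (any(windows[, 1] < epoch[1]) || any(windows[, 2] > epoch[2])) {
    stop("windows must lie within the epoch", call. = FALSE)
  }
  structure(list(mode = mode, windows = windows, epoch = epoch),
            class = "window_spec")
}

#' Slice a neural feature matrix into temporal windows
#'
#' Columns are selected by their time tag: a column belongs to a window
#' when `onset <= time_ms < offset`.
#'
#' @param X items x m feature matrix.
#' @param column_map data.frame with a `time_ms` column.
#' @param spec a [window_spec()].
#' @return List of windows, each `list(X, column_map, window = c(on, off))`.
#' @export
slice_windows <- function(X, column_map, spec) {
  stopifnot(inherits(spec, "window_spec"))
  if (nrow(column_map) != ncol(X)) {
    stop("column_map must describe every column of X", call. = FALSE)
  }
  lapply(seq_len(nrow(spec$windows)), function(i) {
    on <- spec$windows[i, 1]; off <- spec$windows[i, 2]
    sel <- which(column_map$time_ms >= on & column_map$time_ms < off)
    if (length(sel) == 0) {
      stop(sprintf("empty window [%g, %g) ms", on, off), call. = FALSE)
    }
    list(X = X[, sel, drop = FALSE],
         column_map = column_map[sel, , drop = FALSE],
         window = c(onset = unname(on), offset = unname(off)))
  })
}

#' Evaluate predicted coordinates against the embedding
#'
#' Pearson correlation per target dimension, over all items and within each
#' domain separately. Zero-variance subsets yield `NA` (reported missing).
#'
#' @param predicted a `cv_prediction` or items x r matrix.
#' @param embedding target `semantic_embedding`.
#' @param domains per-item domain labels (defaults to the embedding's).
#' @return data.frame with `dimension`, `subset`, `r`.
#' @export
evaluate_predictions <- function(predicted, embedding, domains = embedding$domains) {
  P <- if (inherits(predicted, "cv_prediction")) predicted$predicted else as.matrix(predicted)
  U <- embedding$coords[, seq_len(ncol(P)), drop = FALSE]
  if (nrow(P) != nrow(U)) stop("item count mismatch", call. = FALSE)
  subsets <- c(list(all = rep(TRUE, nrow(U))),
               lapply(stats::setNames(nm = sort(unique(domains))),
                      function(d) domains == d))
  out <- expand.grid(dimension = seq_len(ncol(P)), subset = names(subsets),
                     stringsAsFactors = FALSE)
  out$r <- mapply(function(k, s) {
    idx <- subsets[[s]]
    safe_cor(P[idx, k], U[idx, k])
  }, out$dimension, out$subset)
  out
}

#' Score similarity reconstruction from predicted coordinates
#'
#' The predicted similarity matrix is the outer product of the predicted
#' coordinates; the target is the rank-r reconstruction from the true
#' embedding. For each item, predicted and true similarity rows are
#' correlated over three comparison scopes — all other items, other items
#' in the same domain, other items in the contrasting domain — and the
#' per-item correlations are then averaged over all items, animate items,
#' or inanimate items.
#'
#' @param predicted a `cv_prediction` or items x r coordinate matrix.
#' @param embedding target `semantic_embedding`.
#' @param domains per-item domain labels (defaults to the embedding's).
#' @return data.frame with `group` (item-averaging group), `scope`
#'   (comparison scope), `mean_r`, `n_items`.
#' @export
score_reconstruction <- function(predicted, embedding, domains = embedding$domains) {
  P <- if (inherits(predicted, "cv_prediction")) predicted$predicted else as.matrix(predicted)
  if (ncol(P) != embedding$r) stop("predicted coordinates must have r columns", call. = FALSE)
  pred_sim <- tcrossprod(P)
  true_sim <- tcrossprod(embedding$coords)
  n <- nrow(P)
  doms <- sort(unique(domains))
  scopes <- c("all_others", "same_domain", "other_domain")
  per_item <- matrix(NA_real_, n, length(scopes), dimnames = list(NULL, scopes))
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    sets <- list(
      all_others = others,
      same_domain = setdiff(which(domains == domains[i]), i),
      other_domain = which(domains != domains[i])
    )
    for (s in scopes) {
      idx <- sets[[s]]
      if (length(idx) < 3) {
        stop(sprintf("scope '%s' has fewer than 3 comparison items", s), call. = FALSE)
      }
      per_item[i, s] <- safe_cor(pred_sim[i, idx], true_sim[i, idx])
    }
  }
  groups <- c(list(all = seq_len(n)),
              lapply(stats::setNames(nm = doms), function(d) which(domains == d)))
  out <- expand.grid(group = names(groups), scope = scopes,
                     stringsAsFactors = FALSE)
  out$mean_r <- mapply(function(g, s) mean(per_item[groups[[g]], s]),
                       out$group, out$scope)
  out$n_items <- vapply(groups[out$group], length, integer(1))
  out
}

#' Run a multi-subject windowed decoding study
#'
#' Orchestrates, per subject and per temporal window: nested-CV decoding,
#' coordinate evaluation, and a per-subject permutation null; then
#' aggregates across subjects (unweighted mean with SEM), builds the
#' group-level resampled null per statistic, and reports permutation-mean
#' centered values with empirical p-values and BH-adjusted significance.
#' All (window x dimension x subset) p-values within the run are adjusted
#' as one family.
#'
#' @param subjects named list; each element is `list(X, column_map)` (e.g.
#'   from [flatten_timeseries()] / [make_synthetic_ephys()]).
#' @param embedding target `semantic_embedding` (shared across subjects).
#' @param spec a [window_spec()].
#' @param family `"none"`, `"lasso"`, or `"growl"`.
#' @param search tuning settings passed to [nested_cv_decode()].
#' @param n_perm_subject per-subject permutations (default 100).
#' @param n_group group-level resamples (default 10000).
#' @param k_folds outer folds (default 10).
#' @param retune_permutations re-tune hyperparameters inside permutations;
#'   when `FALSE`, each permutation reuses the configuration chosen most
#'   often across the unpermuted outer folds.
#' @param seed master seed.
#' @return An object of class `rsl_study`: `table` (tidy results:
#'   subject-mean statistic, centered value, p, p_adj per window x
#'   dimension x subset), `per_subject` (observed statistics), `nulls`
#'   (per-subject null matrices), `failed_subjects`.
#' @export
run_study <- function(subjects, embedding, spec, family = "growl",
                      search = list(), n_perm_subject = 100, n_group = 10000,
                      k_folds = 10, retune_permutations = TRUE, seed = 1) {
  stopifnot(inherits(spec, "window_spec"))
  if (nrow(spec$windows) == 0) stop("empty window list", call. = FALSE)
  if (is.null(names(subjects))) names(subjects) <- paste0("S", seq_along(subjects))
  U <- embedding$coords
  domains <- embedding$domains
  fold_plan <- make_fold_plan(embedding$item_ids, domains, k_outer = k_folds,
                              seed = mix_seed(seed, "plan"))
  observed <- list(); nulls <- list(); failed <- character(0)
  for (sj in names(subjects)) {
    res <- tryCatch({
      sub <- subjects[[sj]]
      wins <- slice_windows(sub$X, sub$column_map, spec)
      obs_rows <- list(); null_rows <- list()
      for (wi in seq_along(wins)) {
        w <- wins[[wi]]
        cvp <- nested_cv_decode(w$X, U, fold_plan, family = family,
                                search = search,
                                seed = mix_seed(seed, sj, "decode", wi))
        stat <- decode_statistics(cvp$predicted, U, domains)
        tuned <- NULL
        if (!retune_permutations && family != "none") {
          cfg <- vapply(cvp$chosen, function(p) {
            paste(signif(unlist(p), 6), collapse = "|")
          }, character(1))
          tuned <- cvp$chosen[[which.max(tabulate(match(cfg, unique(cfg))))]]
        }
        nl <- permuted_decode(w$X, U, fold_plan, family = family,
                              search = search, n_perm = n_perm_subject,
                              seed = mix_seed(seed, sj, "perm", wi),
                              retune = retune_permutations,
                              tuned_params = tuned)
        names(stat) <- paste0("w", wi, ".", names(stat))
        colnames(nl) <- paste0("w", wi, ".", colnames(nl))
        obs_rows[[wi]] <- stat
        null_rows[[wi]] <- nl
      }
      list(obs = unlist(obs_rows), null = do.call(cbind, null_rows))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("subject %s failed: %s", sj, conditionMessage(res)))
      failed <- c(failed, sj)
    } else {
      observed[[sj]] <- res$obs
      nulls[[sj]] <- res$null
    }
  }
  if (length(observed) == 0) stop("all subjects failed", call. = FALSE)
  obs_mat <- do.call(rbind, observed)
  stats_ids <- colnames(obs_mat)
  rows <- lapply(seq_along(stats_ids), function(j) {
    id <- stats_ids[j]
    gn <- group_null(lapply(nulls, function(nl) nl[, id]), n_group = n_group,
                     seed = mix_seed(seed, "gn", j))
    # drop subjects with undefined statistic (zero-variance subsets)
    ok <- !is.na(obs_mat[, j])
    grp_mean <- mean(obs_mat[ok, j])
    data.frame(
      statistic = id,
      window = as.integer(sub("^w(\\d+)\\..*$", "\\1", id)),
      dimension = as.integer(sub("^w\\d+\\.dim(\\d+)\\..*$", "\\1", id)),
      subset = sub("^w\\d+\\.dim\\d+\\.", "", id),
      mean = grp_mean,
      sem = sd(obs_mat[ok, j]) / sqrt(sum(ok)),
      centered = center_on_null(grp_mean, gn),
      p = empirical_p(grp_mean, gn),
      stringsAsFactors = FALSE
    )
  })
  table <- do.call(rbind, rows)
  table$p_adj <- fdr_adjust(table$p)
  onoff <- spec$windows[table$window, , drop = FALSE]
  table$onset <- onoff[, 1]; table$offset <- onoff[, 2]
  structure(list(table = table, per_subject = obs_mat, nulls = nulls,
                 failed_subjects = failed, spec = spec, family = family,
                 seed = seed),
            class = "rsl_study")
}
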