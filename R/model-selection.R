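# Nested cross-validation with stratified folds, Hyperband-style
# successive-halving hyperparameter search on the inner loop, and assembly
# of out-of-sample predictions for every item.

#' Stratified fold plan
#'
#' Partitions items into `k_outer` disjoint sets with exact per-fold domain
#' balance (e.g. 100 items, k = 10: ten sets of 5 animate + 5 inanimate).
#' Within each outer fold, the remaining `k_outer - 1` sets serve as the
#' inner-loop folds.
#'
#' @param item_ids item labels.
#' @param domains per-item domain labels (two levels).
#' @param k_outer number of outer folds (default 10).
#' @param seed RNG seed; the plan is deterministic given the seed.
#' @return An object of class `fold_plan`: `assignment` (integer fold id
#'   per item), `k`, `item_ids`, `domains`, `seed`.
#' @export
make_fold_plan <- function(item_ids, domains, k_outer = 10, seed = 1) {
  n <- length(item_ids)
  if (length(domains) != n) stop("domains must match item_ids", call. = FALSE)
  lev <- unique(domains)
  for (d in lev) {
    if (sum(domains == d) %% k_outer != 0) {
      stop(sprintf("cannot balance domain '%s' (%d items) across %d folds",
                   d, sum(domains == d), k_outer), call. = FALSE)
    }
  }
  assignment <- integer(n)
  with_seed(mix_seed(seed, "folds"), {
    for (d in lev) {
      idx <- which(domains == d)
      per <- length(idx) / k_outer
      assignment[sample(idx)] <- rep(seq_len(k_outer), each = per)
    }
  })
  structure(list(assignment = assignment, k = as.integer(k_outer),
                 item_ids = as.character(item_ids),
                 domains = as.character(domains), seed = as.integer(seed)),
            class = "fold_plan")
}

# z-score columns by training statistics; constant columns get scale 1.
standardizer <- function(X_train) {
  mu <- colMeans(X_train)
  sdv <- apply(X_train, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(center = mu, scale = sdv,
       apply = function(X) sweep(sweep(X, 2, mu), 2, sdv, "/"))
}

fit_family <- function(X, U, family, params, max_iter = 10000, tol = 1e-8) {
  if (family == "none") {
    if (nrow(X) > ncol(X)) fit_ols(X, U) else fit_ols(X, U, pseudo_inverse = TRUE)
  } else if (family == "lasso") {
    fit_regularized(X, U, regularizer_spec("lasso", alpha = params$alpha),
                    max_iter = max_iter, tol = tol)
  } else {
    fit_regularized(X, U,
                    regularizer_spec("growl", alpha = params$alpha,
                                     lam = params$lam, omega = params$omega),
                    max_iter = max_iter, tol = tol)
  }
}

#' Inner-loop prediction error for one hyperparameter configuration
#'
#' For each inner fold, fits the decoder on the remaining folds and
#' evaluates the Frobenius norm of true minus predicted coordinates on the
#' held-out fold; returns the mean across inner folds. Standardization
#' statistics are recomputed on each inner training split so no holdout
#' information leaks into the fit.
#'
#' @param X_train,U_train training-set predictors and targets.
#' @param inner_assignment integer fold label per training item.
#' @param family `"none"`, `"lasso"`, or `"growl"`.
#' @param params list with `alpha` (and `lam`, `omega` for grOWL).
#' @param max_iter solver iteration budget.
#' @return Mean holdout Frobenius error (nonnegative); attribute
#'   `any_nonconverged` flags inner fits that hit the budget.
#' @export
inner_loop_score <- function(X_train, U_train, inner_assignment, family, params,
                             max_iter = 10000, tol = 1e-6) {
  folds <- sort(unique(inner_assignment))
  errs <- numeric(length(folds))
  flagged <- FALSE
  for (i in seq_along(folds)) {
    hold <- inner_assignment == folds[i]
    st <- standardizer(X_train[!hold, , drop = FALSE])
    Xs <- st$apply(X_train[!hold, , drop = FALSE])
    Xh <- st$apply(X_train[hold, , drop = FALSE])
    u_mu <- colMeans(U_train[!hold, , drop = FALSE])
    Uc <- sweep(U_train[!hold, , drop = FALSE], 2, u_mu)
    fit <- withCallingHandlers(
      fit_family(Xs, Uc, family, params, max_iter = max_iter, tol = tol),
      warning = function(w) {
        if (grepl("did not converge", conditionMessage(w))) {
          flagged <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    pred <- predict(fit, Xh)
    pred <- sweep(pred, 2, u_mu, "+")
    errs[i] <- sqrt(sum((U_train[hold, , drop = FALSE] - pred)^2))
  }
  out <- mean(errs)
  attr(out, "se") <- sd(errs) / sqrt(length(errs))
  attr(out, "any_nonconverged") <- flagged
  out
}

sample_configs <- function(n, family, bounds, seed) {
  with_seed(seed, {
    draw <- function() exp(runif(1, log(bounds[1]), log(bounds[2])))
    lapply(seq_len(n), function(i) {
      if (family == "lasso") list(alpha = draw(), lam = 0, omega = 0)
      else list(alpha = draw(), lam = draw(), omega = draw())
    })
  })
}

# rule = "min": lowest mean error, ties broken toward smaller alpha then
# smaller omega (prefer simpler models).
# rule = "1se": among configurations whose mean error lies within one
# standard error of the best, prefer the largest alpha (the sparsest model
# whose performance is statistically indistinguishable from the optimum) --
# the selection used for support recovery.
pick_best <- function(configs, scores, ses = rep(0, length(scores)),
                      rule = c("min", "1se")) {
  rule <- match.arg(rule)
  i_min <- which.min(scores)
  if (rule == "1se") {
    cand <- which(scores <= scores[i_min] + ses[i_min])
    a <- vapply(configs[cand], `[[`, numeric(1), "alpha")
    return(cand[which.max(a)])
  }
  best <- min(scores)
  cand <- which(scores <= best + 1e-12)
  if (length(cand) > 1) {
    a <- vapply(configs[cand], `[[`, numeric(1), "alpha")
    cand <- cand[a == min(a)]
    if (length(cand) > 1) {
      o <- vapply(configs[cand], `[[`, numeric(1), "omega")
      cand <- cand[which.min(o)]
    }
  }
  cand[1]
}

#' Hyperband-style hyperparameter search on the inner folds
#'
#' Samples configurations log-uniformly from the search bounds and runs
#' successive halving with ratio `eta`: all configurations are scored with
#' a reduced solver iteration budget, the best `1/eta` fraction advances to
#' an `eta`-fold larger budget, until at most `eta` configurations remain;
#' those finalists are scored at the full budget and the winner selected by
#' `rule`. With `search = "grid"`, every supplied configuration is scored
#' at the full budget (exactly reproducible exhaustive mode).
#'
#' @param X_train,U_train training-set predictors and targets.
#' @param inner_assignment integer inner-fold label per training item.
#' @param family `"lasso"` or `"growl"`.
#' @param search `"hyperband"` or `"grid"`.
#' @param n_configs configurations sampled for hyperband (default 27).
#' @param max_budget full solver iteration budget (default 3000).
#' @param eta halving ratio (default 3).
#' @param bounds log-uniform sampling bounds for `alpha`, `lam`, `omega`
#'   (default `c(1e-4, 1e1)`).
#' @param grid list of configuration lists for `search = "grid"`.
#' @param seed RNG seed for configuration sampling.
#' @param tol solver tolerance used while scoring candidates (looser than
#'   the final refit's, since only the ranking matters here).
#' @param rule winner selection: `"min"` (lowest mean inner error; ties go
#'   to the simpler model) or `"1se"` (sparsest configuration within one
#'   standard error of the best — used for support recovery).
#' @return List with `best` (the selected configuration), `score` (its
#'   inner-loop error at full budget), and `history` (data.frame of all
#'   evaluations).
#' @export
hyperband_search <- function(X_train, U_train, inner_assignment, family,
                             search = c("hyperband", "grid"), n_configs = 27,
                             max_budget = 3000, eta = 3,
                             bounds = c(1e-4, 1e1), grid = NULL, seed = 1,
                             tol = 1e-5, rule = c("min", "1se")) {
  search <- match.arg(search)
  rule <- match.arg(rule)
  history <- list()
  score_all <- function(configs, budget) {
    out <- lapply(configs, function(p) {
      s <- inner_loop_score(X_train, U_train, inner_assignment, family, p,
                            max_iter = budget, tol = tol)
      history[[length(history) + 1]] <<- data.frame(
        alpha = p$alpha, lam = p$lam, omega = p$omega,
        budget = budget, score = as.numeric(s), se = attr(s, "se"))
      s
    })
    list(scores = vapply(out, as.numeric, numeric(1)),
         ses = vapply(out, attr, numeric(1), "se"))
  }
  if (search == "grid") {
    if (is.null(grid) || length(grid) == 0) stop("empty configuration grid", call. = FALSE)
    configs <- grid
    sc <- score_all(configs, max_budget)
  } else {
    if (n_configs < 1) stop("empty bracket: n_configs must be >= 1", call. = FALSE)
    configs <- sample_configs(n_configs, family, bounds, mix_seed(seed, "hyperband"))
    rounds <- max(0, floor(log(length(configs)) / log(eta)))
    budget <- max(1, round(max_budget / eta^rounds))
    sc <- score_all(configs, budget)
    while (length(configs) > eta) {
      keep <- order(sc$scores)[seq_len(max(1, floor(length(configs) / eta)))]
      configs <- configs[keep]
      budget <- min(max_budget, budget * eta)
      sc <- score_all(configs, budget)
    }
    if (budget < max_budget) {
      budget <- max_budget
      sc <- score_all(configs, budget)
    }
  }
  i <- pick_best(configs, sc$scores, sc$ses, rule = rule)
  list(best = configs[[i]], score = sc$scores[i],
       history = do.call(rbind, history))
}

#' Smallest penalty scale that zeroes the whole model
#'
#' For the grOWL penalty, `beta = 0` minimizes the objective iff `alpha`
#' is at least the dual norm of the gradient at zero, `G = X'U / n`:
#' `max_k (sum of the k largest row norms of G) / (w_1 + ... + w_k)`. For
#' the L1 penalty it is `max |G|`. Used to build data-adaptive alpha grids
#' (the path scale), as penalized-regression packages do for their lambda
#' sequences.
#'
#' @param X items x m predictors (standardized).
#' @param U items x r targets (centered).
#' @param weights grOWL weight sequence, or `NULL` for the L1 penalty.
#' @return The critical penalty scale `alpha_max`.
#' @export
penalty_zero_scale <- function(X, U, weights = NULL) {
  G <- crossprod(X, as.matrix(U)) / nrow(X)
  if (is.null(weights)) return(max(abs(G)))
  g <- sort(sqrt(rowSums(G^2)), decreasing = TRUE)
  max(cumsum(g) / cumsum(weights))
}

# Structured grid for support recovery: for each relative decay
# omega_rel (with lam fixed at 1), an alpha path descending from the
# data-derived zeroing scale.
support_grid <- function(X, U, family, omega_rel = c(0, 1, 4), n_alpha = 8,
                         alpha_span = c(0.8, 0.025)) {
  st <- standardizer(X)
  Xs <- st$apply(X)
  Uc <- sweep(as.matrix(U), 2, colMeans(as.matrix(U)))
  configs <- list()
  ratios <- exp(seq(log(alpha_span[1]), log(alpha_span[2]), length.out = n_alpha))
  if (family == "lasso") omega_rel <- 0
  for (o in omega_rel) {
    w <- if (family == "growl") growl_weights(ncol(X), 1, o) else NULL
    amax <- penalty_zero_scale(Xs, Uc, w)
    for (a in amax * ratios) {
      configs[[length(configs) + 1]] <-
        list(alpha = a, lam = if (family == "growl") 1 else 0, omega = o)
    }
  }
  configs
}

#' Recover the signal-carrying feature support
#'
#' Estimates which neural features carry target information. A structured
#' configuration grid is built from the data: for each of a few weight
#' decays, an alpha path descending from the scale at which the whole
#' model is zeroed (see [penalty_zero_scale()]). Every configuration is
#' scored by inner-fold prediction error over the fold plan's sets and the
#' winner chosen with the one-standard-error rule — the sparsest
#' configuration statistically indistinguishable from the
#' prediction-optimal one. That configuration is refit on each outer-fold
#' training set; the support is the set of rows selected in at least
#' `consensus` of the refits, discarding features whose selection is
#' unstable across folds.
#'
#' @param X items x m predictor matrix.
#' @param U items x r target coordinate matrix.
#' @param fold_plan a [make_fold_plan()] plan.
#' @param family `"lasso"` or `"growl"`.
#' @param search optional overrides: `omega_rel`, `n_alpha`, `alpha_span`
#'   for the grid, plus `max_budget`/`tol` for the scoring.
#' @param consensus fraction of fold refits in which a row must be nonzero
#'   (default 0.9).
#' @param complete_groups fill in near-duplicate features of the stable
#'   support: any column whose item-wise correlation with a selected
#'   column reaches `group_r` joins the support. This operationalizes the
#'   redundancy assumption — correlated signal-carrying features stand or
#'   fall together, but a sparse fit may keep only some representatives of
#'   a redundant group. Default `TRUE`.
#' @param group_r correlation threshold for group completion. The default
#'   (`NULL`) is the Bonferroni-controlled Fisher-z critical value at
#'   family-wise level 0.01 over all (selected x candidate) comparisons,
#'   so only above-chance redundancy completes a group; measurement noise
#'   attenuates true duplicate correlations, so a fixed threshold near 1
#'   would miss them.
#' @param seed RNG seed (the procedure is deterministic; kept for
#'   interface symmetry).
#' @param max_iter iteration cap for the per-fold refits.
#' @return List with `support` (column indices), `config` (the tuned
#'   hyperparameters), `counts` (per-column selection counts), and
#'   `per_fold` (the per-fold supports).
#' @export
recover_support <- function(X, U, fold_plan, family = "growl", search = list(),
                            consensus = 0.9, complete_groups = TRUE,
                            group_r = NULL, seed = 1, max_iter = 3000) {
  stopifnot(inherits(fold_plan, "fold_plan"))
  U <- as.matrix(U)
  grid <- do.call(support_grid, c(
    list(X = X, U = U, family = family),
    search[intersect(names(search), c("omega_rel", "n_alpha", "alpha_span"))]
  ))
  args <- c(list(X_train = X, U_train = sweep(U, 2, colMeans(U)),
                 inner_assignment = fold_plan$assignment, family = family,
                 search = "grid", grid = grid, rule = "1se",
                 seed = mix_seed(seed, "support")),
            search[intersect(names(search), c("max_budget", "tol"))])
  tuned <- do.call(hyperband_search, args)
  per_fold <- lapply(seq_len(fold_plan$k), function(f) {
    hold <- fold_plan$assignment == f
    st <- standardizer(X[!hold, , drop = FALSE])
    Utr <- U[!hold, , drop = FALSE]
    fit <- suppressWarnings(
      fit_family(st$apply(X[!hold, , drop = FALSE]),
                 sweep(Utr, 2, colMeans(Utr)), family, tuned$best,
                 max_iter = max_iter, tol = 1e-7)
    )
    nonzero_rows(fit)
  })
  counts <- tabulate(unlist(per_fold), nbins = ncol(X))
  support <- which(counts >= consensus * fold_plan$k)
  if (complete_groups && length(support) > 0) {
    if (is.null(group_r)) {
      n_tests <- length(support) * (ncol(X) - 1)
      z_crit <- stats::qnorm(1 - 0.01 / (2 * n_tests)) / sqrt(nrow(X) - 3)
      group_r <- min(0.95, tanh(z_crit))
    }
    cors <- abs(cor(X[, support, drop = FALSE], X))
    support <- sort(union(support, which(apply(cors >= group_r, 2, any))))
  }
  list(support = support, config = tuned$best, counts = counts,
       per_fold = per_fold)
}

#' Nested cross-validated decoding
#'
#' For each outer fold: tune hyperparameters on the inner folds (the other
#' outer sets), refit on all non-holdout items with the selected
#' configuration, and predict the holdout items. Concatenating across outer
#' folds yields an out-of-sample prediction for every item, each produced
#' by a model never trained on that item. Predictors are z-scored and
#' targets centered with training-fold statistics only.
#'
#' @param X items x m predictor matrix.
#' @param U items x r target coordinate matrix.
#' @param fold_plan a [make_fold_plan()] plan.
#' @param family `"none"` (OLS; no inner tuning), `"lasso"`, or `"growl"`.
#' @param search list of arguments passed to [hyperband_search()] (e.g.
#'   `list(search = "hyperband", n_configs = 9, max_budget = 1000)`), or
#'   `list(fixed = list(alpha=, lam=, omega=))` to skip tuning.
#' @param seed seed controlling configuration sampling.
#' @param max_iter iteration cap for the final per-fold refits.
#' @return An object of class `cv_prediction`: `predicted` (items x r),
#'   `fold` (outer fold per item), `chosen` (per-fold hyperparameters),
#'   `item_ids`, `domains`.
#' @export
nested_cv_decode <- function(X, U, fold_plan, family = c("none", "lasso", "growl"),
                             search = list(), seed = 1, max_iter = 10000) {
  family <- match.arg(family)
  stopifnot(inherits(fold_plan, "fold_plan"))
  U <- as.matrix(U)
  n <- nrow(X)
  if (length(fold_plan$assignment) != n) {
    stop("fold plan does not match the number of items", call. = FALSE)
  }
  predicted <- matrix(NA_real_, n, ncol(U))
  chosen <- vector("list", fold_plan$k)
  for (f in seq_len(fold_plan$k)) {
    hold <- fold_plan$assignment == f
    Xtr <- X[!hold, , drop = FALSE]
    Utr <- U[!hold, , drop = FALSE]
    params <- list(alpha = 0, lam = 0, omega = 0)
    if (family != "none") {
      if (!is.null(search$fixed)) {
        params <- search$fixed
      } else {
        args <- c(list(X_train = Xtr, U_train = Utr,
                       inner_assignment = fold_plan$assignment[!hold],
                       family = family, seed = mix_seed(seed, "outer", f)),
                  search)
        tuned <- do.call(hyperband_search, args)
        params <- tuned$best
      }
    }
    chosen[[f]] <- params
    st <- standardizer(Xtr)
    u_mu <- colMeans(Utr)
    fit <- suppressWarnings(
      fit_family(st$apply(Xtr), sweep(Utr, 2, u_mu), family, params,
                 max_iter = max_iter)
    )
    pred <- predict(fit, st$apply(X[hold, , drop = FALSE]))
    predicted[hold, ] <- sweep(pred, 2, u_mu, "+")
  }
  dimnames(predicted) <- list(fold_plan$item_ids, colnames(U))
  structure(list(predicted = predicted, fold = fold_plan$assignment,
                 chosen = chosen, item_ids = fold_plan$item_ids,
                 domains = fold_plan$domains),
            class = "cv_prediction")
}
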