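# Permutation-based inference: per-subject null distributions from
# row-permuted targets, group-level resampled nulls, empirical p-values,
# FDR control, and permutation-mean centering.

#' Default decoding statistics: per-dimension, per-subset correlations
#'
#' Pearson correlation between predicted and true coordinates for each
#' target dimension, over all items and within each domain.
#'
#' @param predicted items x r matrix of holdout predictions.
#' @param U items x r true coordinates.
#' @param domains per-item domain labels (or `NULL` for all-items only).
#' @return Named numeric vector, e.g. `dim1.all`, `dim1.animate`, ...
#' @export
decode_statistics <- function(predicted, U, domains = NULL) {
  U <- as.matrix(U); predicted <- as.matrix(predicted)
  subsets <- list(all = rep(TRUE, nrow(U)))
  if (!is.null(domains)) {
    for (d in sort(unique(domains))) subsets[[d]] <- domains == d
  }
  out <- c()
  for (k in seq_len(ncol(U))) {
    for (s in names(subsets)) {
      idx <- subsets[[s]]
      out[sprintf("dim%d.%s", k, s)] <- safe_cor(predicted[idx, k], U[idx, k])
    }
  }
  out
}

#' Per-subject permutation null via re-decoding permuted targets
#'
#' Repeats the full nested-CV decode with the rows of the target matrix
#' randomly permuted, once per permutation, and records the evaluation
#' statistics. The same row permutation is applied to all dimensions and
#' reused across subsets within a run, so the statistics share a coherent
#' null. By default hyperparameters are re-tuned inside every permutation
#' (conservative); set `retune = FALSE` with `tuned_params` to reuse a
#' fixed configuration.
#'
#' @param X items x m predictors.
#' @param U items x r targets.
#' @param fold_plan a [make_fold_plan()] plan.
#' @param family,search,max_iter passed to [nested_cv_decode()].
#' @param n_perm number of permutations (>= 1).
#' @param seed seed controlling the permutations.
#' @param statistic_fun function `(predicted, U, domains) -> named vector`;
#'   defaults to [decode_statistics()].
#' @param retune re-tune hyperparameters per permutation (default `TRUE`).
#' @param tuned_params fixed configuration used when `retune = FALSE`.
#' @return Matrix `n_perm` x n_statistics of null statistic values.
#' @export
permuted_decode <- function(X, U, fold_plan, family = "none", search = list(),
                            n_perm = 100, seed = 1,
                            statistic_fun = decode_statistics,
                            retune = TRUE, tuned_params = NULL, max_iter = 10000) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  U <- as.matrix(U)
  n <- nrow(U)
  if (!retune) {
    if (is.null(tuned_params) && family != "none") {
      stop("retune = FALSE requires tuned_params", call. = FALSE)
    }
    search <- list(fixed = tuned_params)
  }
  rows <- vector("list", n_perm)
  for (p in seq_len(n_perm)) {
    perm <- with_seed(mix_seed(seed, "perm", p), sample(n))
    cvp <- nested_cv_decode(X, U[perm, , drop = FALSE], fold_plan,
                            family = family, search = search,
                            seed = mix_seed(seed, "permfit", p),
                            max_iter = max_iter)
    rows[[p]] <- statistic_fun(cvp$predicted, U[perm, , drop = FALSE],
                               fold_plan$domains)
  }
  do.call(rbind, rows)
}

#' Group-level resampled null distribution
#'
#' Draws one value uniformly from each subject's null distribution and
#' averages across subjects, `n_group` times.
#'
#' @param per_subject_stats list (one element per subject) of numeric null
#'   statistic vectors.
#' @param n_group number of resampled group means (default 10000).
#' @param seed RNG seed.
#' @return Numeric vector of length `n_group`.
#' @export
group_null <- function(per_subject_stats, n_group = 10000, seed = 1) {
  if (length(per_subject_stats) == 0) stop("empty subject list", call. = FALSE)
  with_seed(mix_seed(seed, "groupnull"), {
    draws <- vapply(per_subject_stats, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) stop("a subject has an empty null distribution", call. = FALSE)
      sample(v, n_group, replace = TRUE)
    }, numeric(n_group))
    if (n_group == 1) draws <- matrix(draws, nrow = 1)
    rowMeans(draws)
  })
}

#' One-tailed empirical p-value
#'
#' `p = (b + 1) / (m + 1)` with `b` the number of null values strictly
#' larger than the observed statistic and `m` the null size, so `p` lies in
#' `(0, 1]` and can never be exactly zero.
#'
#' @param observed observed statistic (scalar).
#' @param null_vector nonempty numeric null distribution.
#' @return p-value in `(0, 1]`.
#' @export
empirical_p <- function(observed, null_vector) {
  if (length(null_vector) == 0) stop("null_vector must be nonempty", call. = FALSE)
  if (any(is.na(c(observed, null_vector)))) stop("NaN/NA in inputs", call. = FALSE)
  (sum(null_vector > observed) + 1) / (length(null_vector) + 1)
}

#' FDR adjustment of permutation p-values
#'
#' Benjamini-Hochberg step-up by default; Benjamini-Yekutieli available for
#' robustness under arbitrary dependence. All p-values passed in one call
#' form one adjustment family.
#'
#' @param p_values raw p-values in `(0, 1]`.
#' @param method `"BH"` (default) or `"BY"`.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = method)
}

#' Center an observed statistic on its permutation-null mean
#'
#' Cross-validated correlations are negatively biased under the null, so
#' observed values are reported relative to the mean of their permutation
#' distribution.
#'
#' @param observed observed statistic(s).
#' @param null_vector nonempty null distribution.
#' @return `observed - mean(null_vector)`.
#' @export
center_on_null <- function(observed, null_vector) {
  if (length(null_vector) == 0) stop("null_vector must be nonempty", call. = FALSE)
  observed - mean(null_vector)
}
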