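# RSA baseline: neural similarity matrices and their correlation with a
# target RSM, plus the simulation sweep reproducing the noise curves.

#' Neural similarity matrix from an item-by-feature matrix
#'
#' Computes pairwise pattern similarities between item rows. The default
#' measure is the Pearson correlation between item pattern vectors;
#' `"cosine_centered"` first centers each pattern (the two coincide).
#'
#' @param X items x features numeric matrix.
#' @param subset optional item ids or indices restricting the matrix.
#' @param method `"pearson"` or `"cosine_centered"`.
#' @return A `similarity_matrix` of kind `"neural"`.
#' @export
compute_nsm <- function(X, subset = NULL, method = c("pearson", "cosine_centered")) {
  method <- match.arg(method)
  stopifnot_matrix(X)
  if (!is.null(subset)) {
    X <- X[subset, , drop = FALSE]
  }
  if (nrow(X) < 3) stop("need at least 3 items for an NSM", call. = FALSE)
  if (ncol(X) < 2) stop("need at least 2 features for an NSM", call. = FALSE)
  Xc <- X - rowMeans(X)  # center each item pattern
  nrm <- sqrt(rowSums(Xc^2))
  if (any(nrm == 0)) {
    bad <- rownames(X)[nrm == 0] %||% which(nrm == 0)
    stop("degenerate constant pattern for item(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  S <- tcrossprod(Xc / nrm)
  S <- (S + t(S)) / 2
  S[S > 1] <- 1
  S[S < -1] <- -1
  diag(S) <- 1
  similarity_matrix(S, item_ids = rownames(X), kind = "neural")
}

#' Correlate a neural and a target similarity matrix
#'
#' The correlation is computed over the strictly lower triangles (diagonal
#' excluded) of the two matrices, which must share item set and order.
#'
#' @param nsm,rsm `similarity_matrix` objects (or square matrices) over the
#'   same items in the same order.
#' @param method `"pearson"` (simulation studies) or `"spearman"` (the RSA
#'   comparison on reconstructed similarities).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
rsa_correlation <- function(nsm, rsm, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  A <- if (inherits(nsm, "similarity_matrix")) nsm$values else nsm
  B <- if (inherits(rsm, "similarity_matrix")) rsm$values else rsm
  if (!all(dim(A) == dim(B))) stop("similarity matrices must match in size", call. = FALSE)
  ia <- if (inherits(nsm, "similarity_matrix")) nsm$item_ids else rownames(A)
  ib <- if (inherits(rsm, "similarity_matrix")) rsm$item_ids else rownames(B)
  if (!is.null(ia) && !is.null(ib) && !identical(ia, ib)) {
    stop("item sets/order differ between matrices", call. = FALSE)
  }
  safe_cor(lower_tri(A), lower_tri(B), method = method, strict = TRUE)
}

#' Simulation sweep: RSA under five signal conditions and graded noise
#'
#' For every (condition, noise level, repetition) a simulated feature set is
#' generated, its NSM computed, and the NSM-RSM Pearson correlation
#' recorded. Per-level means with t-based 95% confidence intervals over the
#' repetitions summarize the sweep.
#'
#' @param embedding target `semantic_embedding` (with domains).
#' @param conditions list of [signal_condition()] objects (default all five).
#' @param noise a [noise_spec()].
#' @param rsm target `similarity_matrix` to correlate against; supply the
#'   full cosine RSM when available. If `NULL`, the rank-r reconstruction
#'   from the embedding is used.
#' @return A list with `results` (data.frame: condition, level, rep, rho)
#'   and `summary` (data.frame: condition, level, mean_rho, ci_lo, ci_hi).
#' @export
run_simulation_study1 <- function(embedding, conditions = standard_conditions(),
                                  noise = noise_spec(), rsm = NULL) {
  if (is.null(rsm)) rsm <- reconstruct_similarity(embedding)
  R <- if (inherits(rsm, "similarity_matrix")) rsm$values else rsm
  rows <- list()
  for (cond in conditions) {
    for (li in seq_along(noise$levels)) {
      for (rep in seq_len(noise$reps)) {
        X <- make_condition_dataset(
          embedding, cond, noise$levels[li],
          seed = mix_seed(noise$seed, cond$name, li, rep)
        )
        nsm <- compute_nsm(X)
        rho <- safe_cor(lower_tri(nsm$values), lower_tri(R))
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond$name, level = noise$levels[li], level_index = li,
          rep = rep, rho = rho, stringsAsFactors = FALSE
        )
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(
    split(results, list(results$condition, results$level_index), drop = TRUE),
    function(d) {
      m <- mean(d$rho)
      se <- sd(d$rho) / sqrt(nrow(d))
      tq <- qt(0.975, df = nrow(d) - 1)
      data.frame(condition = d$condition[1], level = d$level[1],
                 level_index = d$level_index[1], mean_rho = m,
                 ci_lo = m - tq * se, ci_hi = m + tq * se,
                 stringsAsFactors = FALSE)
    }
  ))
  summary <- summary[order(summary$condition, summary$level_index), ]
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}
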