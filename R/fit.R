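# Multitask linear decoders: OLS and proximal-gradient (FISTA) fits of
#     (1/(2n)) ||U - X beta||_F^2 + alpha * H(beta)
# with H the grOWL penalty or the L1 norm. The 1/(2n) loss normalization
# makes alpha comparable across window sizes.

#' Regularizer specification
#'
#' @param family `"growl"`, `"lasso"`, or `"none"`.
#' @param alpha overall penalty scale, `>= 0`. Must be 0 for `"none"`.
#' @param lam baseline row-sparsity weight (grOWL only).
#' @param omega weight-decay range coupling correlated features (grOWL
#'   only; unused for `"lasso"`).
#' @return An object of class `regularizer_spec`.
#' @export
regularizer_spec <- function(family = c("growl", "lasso", "none"),
                             alpha = 0, lam = 0, omega = 0) {
  family <- match.arg(family)
  if (alpha < 0 || lam < 0 || omega < 0) {
    stop("alpha, lam and omega must be nonnegative", call. = FALSE)
  }
  if (family == "none" && alpha != 0) stop("family 'none' requires alpha = 0", call. = FALSE)
  structure(list(family = family, alpha = alpha, lam = lam, omega = omega),
            class = "regularizer_spec")
}

# Squared spectral norm by deterministic power iteration on X'X, with a
# small safety factor so the FISTA step 1/L stays conservative. Much
# cheaper than a full SVD when m is large.
spectral_norm_sq <- function(X, iters = 40, safety = 1.02) {
  m <- ncol(X)
  if (m == 0 || nrow(X) == 0) return(0)
  v <- colMeans(X) + seq_len(m) / m  # deterministic, generic start
  nv <- sqrt(sum(v^2))
  if (nv == 0) v[1] <- 1 else v <- v / nv
  lam <- 0
  for (i in seq_len(iters)) {
    w <- crossprod(X, X %*% v)
    lam_new <- sqrt(sum(w^2))
    if (lam_new == 0) return(0)
    v <- as.vector(w) / lam_new
    if (i > 5 && abs(lam_new - lam) < 1e-10 * lam_new) {
      lam <- lam_new
      break
    }
    lam <- lam_new
  }
  lam * safety
}

penalty_value <- function(beta, reg, weights = NULL) {
  if (reg$family == "none" || reg$alpha == 0) return(0)
  if (reg$family == "lasso") return(reg$alpha * sum(abs(beta)))
  reg$alpha * growl_penalty(beta, weights)
}

#' Ordinary least-squares multitask decoder
#'
#' Fits `beta` minimizing `||U - X beta||_F^2`. Requires more items than
#' features (the overdetermined regime) unless `pseudo_inverse = TRUE`, in
#' which case the minimum-norm solution is returned; with fewer items than
#' features infinitely many coefficient matrices fit the training data
#' perfectly, so the unregularized problem is not identifiable.
#'
#' @param X items x m predictor matrix.
#' @param U items x r target coordinate matrix.
#' @param pseudo_inverse opt in to the minimum-norm solution when `X` is
#'   rank-deficient or has more columns than rows.
#' @return An object of class `rsl_decoder` with elements `beta` (m x r),
#'   `regularizer`, and `fit_log`.
#' @export
fit_ols <- function(X, U, pseudo_inverse = FALSE) {
  stopifnot_matrix(X); stopifnot_matrix(U)
  U <- as.matrix(U)
  if (nrow(X) != nrow(U)) stop("X and U must have matching rows", call. = FALSE)
  qrX <- qr(X)
  deficient <- nrow(X) <= ncol(X) || qrX$rank < ncol(X)
  if (deficient && !pseudo_inverse) {
    stop("X is rank-deficient (or has more features than items): there exist ",
         "infinite solutions. Regularize, or opt in with pseudo_inverse = TRUE.",
         call. = FALSE)
  }
  beta <- if (deficient) {
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% U) / sv$d[pos])
  } else {
    qr.coef(qrX, U)
  }
  dimnames(beta) <- list(colnames(X), colnames(U))
  new_decoder(beta, regularizer_spec("none"),
              fit_log = list(method = "ols", iterations = 0L, converged = TRUE,
                             objective = sum((U - X %*% beta)^2) / (2 * nrow(X))))
}

new_decoder <- function(beta, regularizer, fit_log, weights = NULL,
                        standardization = NULL) {
  structure(list(beta = beta, regularizer = regularizer, weights = weights,
                 fit_log = fit_log, standardization = standardization),
            class = "rsl_decoder")
}

#' Regularized multitask decoder via accelerated proximal gradient
#'
#' Minimizes `(1/(2n)) ||U - X beta||_F^2 + alpha * H(beta)` (grOWL) or
#' `... + alpha * ||beta||_1` (LASSO) with FISTA: fixed step `1/L` where
#' `L = sigma_max(X)^2 / n`, monotone restart when the objective increases,
#' initialization at zero, and stopping when the relative objective change
#' falls below `tol`.
#'
#' @param X items x m predictor matrix.
#' @param U items x r target matrix.
#' @param regularizer a [regularizer_spec()].
#' @param max_iter iteration cap (default 10000).
#' @param tol relative objective-change stopping tolerance (default 1e-8).
#' @param keep_objective record the objective trajectory in the fit log.
#' @return An `rsl_decoder`; `fit_log$converged` is `FALSE` (with a
#'   warning) if `max_iter` was reached first.
#' @export
fit_regularized <- function(X, U, regularizer, max_iter = 10000, tol = 1e-8,
                            keep_objective = FALSE) {
  stopifnot_matrix(X); stopifnot_matrix(U)
  U <- as.matrix(U)
  n <- nrow(X); m <- ncol(X); r <- ncol(U)
  if (nrow(U) != n) stop("X and U must have matching rows", call. = FALSE)
  stopifnot(inherits(regularizer, "regularizer_spec"))
  reg <- regularizer
  if (reg$family == "none" || reg$alpha == 0) {
    if (n > m) return(fit_ols(X, U))
    # penalty-free limit in the underdetermined regime: minimum-norm fit
    return(fit_ols(X, U, pseudo_inverse = TRUE))
  }
  weights <- if (reg$family == "growl") growl_weights(m, reg$lam, reg$omega)
             else rep(1, m)
  L <- spectral_norm_sq(X) / n
  if (L == 0) L <- 1
  fam <- if (reg$family == "lasso") 1L else 0L
  sol <- fista_solve(X, U, weights, reg$alpha, fam, 1 / L,
                     as.integer(max_iter), tol, keep_objective)
  if (!sol$converged) {
    warning(sprintf("FISTA did not converge in %d iterations (rel change %.2e)",
                    max_iter, sol$rel_change))
  }
  beta <- sol$beta
  dimnames(beta) <- list(colnames(X), colnames(U))
  new_decoder(beta, reg,
              fit_log = list(method = "fista", iterations = sol$iterations,
                             restarts = sol$restarts, converged = sol$converged,
                             objective = sol$objective,
                             objective_trace = if (keep_objective) sol$objective_trace),
              weights = if (reg$family == "growl") weights)
}

#' Predict coordinates for new items
#'
#' @param object an `rsl_decoder`.
#' @param newdata items x m matrix with the same columns as the training
#'   predictors.
#' @param ... unused.
#' @return items x r matrix of predicted coordinates.
#' @export
predict.rsl_decoder <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$beta)) {
    stop(sprintf("newdata has %d columns but the decoder expects %d",
                 ncol(newdata), nrow(object$beta)), call. = FALSE)
  }
  newdata %*% object$beta
}

#' Indices of nonzero coefficient rows
#'
#' Rows of `beta` that survive the row-sparse penalty; with grOWL these are
#' exact zeros from the proximal step.
#'
#' @param model an `rsl_decoder`.
#' @return Integer vector of row indices with any nonzero coefficient.
#' @export
nonzero_rows <- function(model) {
  which(rowSums(abs(model$beta)) > 0)
}

#' @export
print.rsl_decoder <- function(x, ...) {
  cat(sprintf("<rsl_decoder> %d features x %d dimensions, family=%s, %d/%d nonzero rows\n",
              nrow(x$beta), ncol(x$beta), x$regularizer$family,
              length(nonzero_rows(x)), nrow(x$beta)))
  invisible(x)
}
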