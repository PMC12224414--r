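# The grOWL penalty and its proximal operator. The penalty on a coefficient
# matrix beta (features x target dimensions) is
#     H(beta) = sum_i w_i * rho_(i),
# where rho_(i) are the row L2 norms sorted in nonincreasing order and w is
# a nonincreasing, nonnegative weight sequence. With constant weights this
# is the group LASSO on rows; the OSCAR-style linear decay couples
# correlated features by pulling their row norms toward common values.

#' grOWL weight sequence
#'
#' Linear (OSCAR-style) decay `w_i = lam + omega * (m - i) / (m - 1)`, so
#' `w_1 = lam + omega` and `w_m = lam`. `lam` sets the baseline
#' row-sparsity pressure applied to every row; `omega` sets the decay range
#' that encourages correlated features to share coefficient magnitudes.
#'
#' @param m number of rows (neural features).
#' @param lam baseline weight, `>= 0`.
#' @param omega decay range, `>= 0`.
#' @return Nonincreasing, nonnegative numeric vector of length `m`.
#' @export
growl_weights <- function(m, lam, omega) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (lam < 0 || omega < 0) stop("lam and omega must be nonnegative", call. = FALSE)
  if (m == 1) return(lam + omega)
  lam + omega * (m - seq_len(m)) / (m - 1)
}

#' grOWL penalty value
#'
#' @param beta coefficient matrix (m x r) or numeric vector of row norms.
#' @param weights nonincreasing, nonnegative weights of length m.
#' @return `sum(weights * sort(row_norms, decreasing = TRUE))`.
#' @export
growl_penalty <- function(beta, weights) {
  rho <- if (is.matrix(beta)) sqrt(rowSums(beta^2)) else abs(beta)
  if (length(weights) != length(rho)) {
    stop("weights must have one entry per row of beta", call. = FALSE)
  }
  sum(weights * sort(rho, decreasing = TRUE))
}

# Proximal operator of the ordered-weighted L1 norm on a nonnegative vector
# of row norms: argmin_x 1/2 ||x - v||^2 + sum_i tw_i x_(i), x >= 0.
# Sort v descending, subtract the weights, project onto the nonincreasing
# cone (PAVA), clip at zero, undo the sort.
prox_owl <- function(v, tw) {
  ord <- order(v, decreasing = TRUE)
  z <- v[ord] - tw
  x <- pava_nonincreasing(z)
  x[x < 0] <- 0
  out <- numeric(length(v))
  out[ord] <- x
  out
}

#' Proximal operator of the grOWL penalty
#'
#' Computes `argmin_B 1/2 ||B - V||_F^2 + step * H(B)` where `H` is the
#' grOWL penalty with the given weights. The row norms of `V` pass through
#' the ordered-weighted-L1 prox (sort descending, subtract `step * weights`,
#' pool-adjacent-violators projection onto the nonincreasing cone, clip at
#' zero, undo the sort) and each row of `V` is rescaled to its new norm.
#' Rows whose new norm is zero become exactly zero; zero input rows stay
#' zero.
#'
#' @param V numeric matrix (m x r).
#' @param weights nonincreasing, nonnegative weights of length m.
#' @param step positive step size (the prox scales the penalty by `step`).
#' @return Matrix of the same shape as `V`.
#' @export
prox_growl <- function(V, weights, step = 1) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  V <- as.matrix(V)
  if (length(weights) != nrow(V)) {
    stop("weights must have one entry per row of V", call. = FALSE)
  }
  if (any(diff(weights) > 1e-12) || any(weights < 0)) {
    stop("weights must be nonincreasing and nonnegative", call. = FALSE)
  }
  v <- sqrt(rowSums(V^2))
  x <- prox_owl(v, step * weights)
  scale <- ifelse(v > 0, x / v, 0)
  out <- V * scale
  out[x == 0, ] <- 0
  out
}

#' Proximal operator of the L1 penalty (soft threshold)
#'
#' @param V numeric matrix or vector.
#' @param lam_eff nonnegative effective threshold (`step * alpha` inside the
#'   solver).
#' @return Elementwise soft-thresholded copy of `V`.
#' @export
prox_lasso <- function(V, lam_eff) {
  if (lam_eff < 0) stop("lam_eff must be nonnegative", call. = FALSE)
  sign(V) * pmax(abs(V) - lam_eff, 0)
}
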