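# Independent oracles.
#
# oracle_prox_growl: brute-force minimizer of the prox objective
#   1/2 ||B - V||_F^2 + step * sum_i w_i rho_(i)
# by enumerating all assignments of rows to sorted-weight positions. For a
# fixed assignment (permutation) the problem in row-norm space has an
# identity Hessian, so the constrained minimizer is the Euclidean
# projection of the unconstrained one onto the ordered nonnegative cone --
# computed with base R's stats::isoreg (an implementation unrelated to the
# package's PAVA) followed by clipping at zero. The candidate with the
# smallest exact objective over all permutations is returned. Feasible for
# m <= 6.

iso_nonincreasing <- function(z) {
  rev(stats::isoreg(rev(z))$yf)
}

growl_objective_bruteforce <- function(B, V, weights, step) {
  rho <- sqrt(rowSums(B^2))
  # penalty by maximization over permutations (definition of OWL as a
  # support function), not by sorting
  perms <- all_perms(length(rho))
  H <- max(vapply(perms, function(p) sum(weights * rho[p]), numeric(1)))
  0.5 * sum((B - V)^2) + step * H
}

all_perms <- function(m) {
  if (m == 1) return(list(1L))
  out <- list()
  for (p in all_perms(m - 1)) {
    for (pos in 0:(m - 1)) {
      out[[length(out) + 1]] <- append(p, m, after = pos)
    }
  }
  out
}

oracle_prox_growl <- function(V, weights, step) {
  m <- nrow(V)
  v <- sqrt(rowSums(V^2))
  unit <- V / ifelse(v > 0, v, 1)
  best <- NULL
  best_obj <- Inf
  for (p in all_perms(m)) {
    # rows p[1], p[2], ... occupy weight positions 1, 2, ...
    z <- v[p] - step * weights
    rho_sorted <- pmax(iso_nonincreasing(z), 0)
    rho <- numeric(m)
    rho[p] <- rho_sorted
    B <- unit * rho
    obj <- growl_objective_bruteforce(B, V, weights, step)
    if (obj < best_obj) {
      best_obj <- obj
      best <- B
    }
  }
  list(B = best, objective = best_obj)
}

# Reference solution of the full regularized objective
#   1/(2n) ||U - X beta||_F^2 + alpha * H(beta)
# via an independently written plain ISTA in Python (numpy +
# scipy.optimize.isotonic_regression). Returns the reference optimum
# objective value.
reference_growl_objective <- function(X, U, alpha, lam, omega, iters = 50000) {
  dir <- withr::local_tempdir()
  write.table(X, file.path(dir, "X.csv"), sep = ",", row.names = FALSE, col.names = FALSE)
  write.table(U, file.path(dir, "U.csv"), sep = ",", row.names = FALSE, col.names = FALSE)
  out <- system2("python", c(test_path("ista_reference.py"),
                             file.path(dir, "X.csv"), file.path(dir, "U.csv"),
                             format(alpha, digits = 17), format(lam, digits = 17),
                             format(omega, digits = 17), as.character(iters)),
                 stdout = TRUE)
  as.numeric(tail(out, 1))
}

objective_value <- function(X, U, beta, reg) {
  n <- nrow(X)
  pen <- if (reg$family == "lasso") {
    reg$alpha * sum(abs(beta))
  } else if (reg$family == "growl") {
    reg$alpha * growl_penalty(beta, growl_weights(nrow(beta), reg$lam, reg$omega))
  } else 0
  sum((U - X %*% beta)^2) / (2 * n) + pen
}
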