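"""Reference solver for the grOWL-regularized multitask regression objective.

Plain (non-accelerated) proximal gradient with step 1/L, written
independently of the R implementation; the isotonic projection inside the
ordered-weighted prox uses scipy.optimize.isotonic_regression.

Usage: python ista_reference.py X.csv U.csv alpha lam omega iters
Prints the final objective value on the last line.
"""
import sys

import numpy as np
from scipy.optimize import isotonic_regression


def growl_weights(m, lam, omega):
    if m == 1:
        return np.array([lam + omega])
    i = np.arange(1, m + 1)
    return lam + omega * (m - i) / (m - 1)


def prox(V, tw):
    v = np.linalg.norm(V, axis=1)
    order = np.argsort(-v)
    z = v[order] - tw
    x = isotonic_regression(z, increasing=False).x
    x = np.maximum(x, 0.0)
    new = np.empty_like(v)
    new[order] = x
    scale = np.where(v > 0, new / np.where(v > 0, v, 1.0), 0.0)
    return V * scale[:, None]


def objective(X, U, B, alpha, w):
    n = X.shape[0]
    rho = np.sort(np.linalg.norm(B, axis=1))[::-1]
    return ((U - X @ B) ** 2).sum() / (2 * n) + alpha * (w * rho).sum()


def main():
    X = np.loadtxt(sys.argv[1], delimiter=",", ndmin=2)
    U = np.loadtxt(sys.argv[2], delimiter=",", ndmin=2)
    alpha, lam, omega = map(float, sys.argv[3:6])
    iters = int(sys.argv[6])
    n, m = X.shape
    w = growl_weights(m, lam, omega)
    L = np.linalg.svd(X, compute_uv=False)[0] ** 2 / n
    step = 1.0 / L
    B = np.zeros((m, U.shape[1]))
    XtU = X.T @ U / n
    for _ in range(iters):
        grad = X.T @ (X @ B) / n - XtU
        B = prox(B - step * grad, step * alpha * w)
    print(f"{objective(X, U, B, alpha, w):.17g}")


if __name__ == "__main__":
    main()
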