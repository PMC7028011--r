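# Independent brute-force minimizer for the per-column smoothing program:
# projected gradient descent over the probability simplex.  Shares no code
# with qp_infer_column (which uses the exact equality-constrained solve).

# Euclidean projection of a vector onto the probability simplex
# (sort-and-threshold algorithm).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

# Objective of the smoothing program for one base position.
smoothing_objective <- function(X, S, W, alpha) {
  Wsym <- W
  pen <- 0
  idx <- which(W > 0, arr.ind = TRUE)
  if (nrow(idx) > 0)
    pen <- sum(W[idx] * rowSums((X[idx[, 1], , drop = FALSE] -
                                 X[idx[, 2], , drop = FALSE])^2))
  alpha * sum((S - X)^2) + (1 - alpha) * pen
}

# Projected-gradient minimizer; S and W are n x 4 and n x n matrices over
# the same node ordering.  Returns the n x 4 minimizer.
oracle_qp <- function(S, W, alpha, iters = 6000) {
  Wsym <- W + t(W)
  D <- diag(rowSums(Wsym), nrow(S))
  L <- 2 * alpha + 2 * (1 - alpha) * 2 * max(rowSums(Wsym), 1e-12)
  step <- 1 / L
  X <- S
  for (t in seq_len(iters)) {
    grad <- 2 * alpha * (X - S) + 2 * (1 - alpha) * ((D - Wsym) %*% X)
    X <- X - step * grad
    X <- t(apply(X, 1, project_simplex))
  }
  X
}

# Fixed point of the anchored propagation, solved as a linear system
# (independent of the iterative implementation).
oracle_lpa_fixed_point <- function(S, W, alpha) {
  n <- nrow(S)
  solve(diag(n) - (1 - alpha) * W, alpha * S)
}
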