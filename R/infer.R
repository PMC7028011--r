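# Per-column solvers.  Both operate on an n x 4 matrix of probability
# vectors (rows = cores, columns = A/C/G/T) for a single binding-site
# position, coupled through one similarity graph.

.check_prob_rows <- function(S, tol = 1e-6) {
  if (!is.matrix(S) || ncol(S) != 4L || is.null(rownames(S)))
    stop("S_cols must be an n x 4 matrix with core-sequence rownames")
  if (any(S < -tol) || any(abs(rowSums(S) - 1) > tol))
    stop("every row of S_cols must be a probability 4-vector")
  invisible(S)
}

#' Revise one PWM column across all cores by quadratic programming
#'
#' Minimizes
#' `alpha * sum_a ||S_a - Shat_a||^2 +
#'  (1 - alpha) * sum_{a,a'} w(a, a') * ||Shat_a - Shat_{a'}||^2`
#' over per-core probability 4-vectors `Shat_a` constrained to the simplex
#' (entries in \[0, 1\], summing to 1).  The graph weights are the per-node
#' normalized out-weights; the double sum runs over ordered pairs, so the
#' directed weights enter symmetrically.
#'
#' The program is strictly convex and its box constraints are never active:
#' the stationary point solves `(alpha * I + (1 - alpha) * L) X = alpha * S`
#' with `L = D - (W + W')` the symmetrized graph Laplacian, and
#' `alpha * (alpha * I + (1 - alpha) * L)^-1` is a nonnegative row-stochastic
#' averaging operator, so the equality-constrained minimizer already lies on
#' the simplex.  The solver therefore performs the exact linear solve and
#' verifies feasibility afterwards; entries within `-feasibility_tol` of 0
#' are clipped and the row renormalized, larger violations are an error.
#'
#' @param S_cols n x 4 matrix of probability vectors with core rownames.
#' @param graph a [similarity_graph()]; its nodes must be a subset of the
#'   rownames of `S_cols`.  Cores absent from the graph, and isolated graph
#'   nodes, are returned unchanged.
#' @param alpha fidelity parameter in (0, 1\]; `alpha = 1` returns the input.
#' @param feasibility_tol numerical feasibility tolerance (default 1e-9).
#' @return n x 4 matrix of revised probability vectors, same rownames.
#' @export
qp_infer_column <- function(S_cols, graph, alpha, feasibility_tol = 1e-9) {
  .check_prob_rows(S_cols)
  stopifnot(inherits(graph, "similarity_graph"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  if (!all(graph$nodes %in% rownames(S_cols)))
    stop("graph nodes must be a subset of the cores in S_cols")
  if (alpha == 1) return(S_cols)
  touched <- unique(c(graph$edges$from, graph$edges$to))
  if (length(touched) == 0L) return(S_cols)
  W <- weight_matrix(graph, nodes = touched)
  Wsym <- W + t(W)
  A <- diag(alpha, length(touched)) + (1 - alpha) * (diag(rowSums(Wsym)) - Wsym)
  X <- solve(A, alpha * S_cols[touched, , drop = FALSE])
  bad <- X < -feasibility_tol | X > 1 + feasibility_tol |
    abs(rowSums(X) - 1) > sqrt(feasibility_tol)
  if (any(bad))
    stop(sprintf("QP solution infeasible beyond tolerance (max violation %.3g)",
                 max(abs(pmin(X, 0)), abs(pmax(X - 1, 0)))))
  X[X < 0] <- 0
  X <- X / rowSums(X)
  out <- S_cols
  out[touched, ] <- X
  out
}

#' Revise one PWM column across all cores by label propagation (adsorption)
#'
#' Iteratively blends each core's current column with its graph neighbors'.
#' The default `anchored` variant iterates
#' `Shat^(t) = alpha * S + (1 - alpha) * W Shat^(t-1)` from `Shat^(0) = S`
#' until the maximum entry change drops below `tol` or `max_iter` is
#' reached; it is the absorbing-random-walk form in which every walk
#' re-enters the initial estimate with probability alpha, and for alpha > 0
#' it is a contraction with a unique fixed point.  The `literal` variant
#' iterates `Shat^(t) = alpha * Shat^(t-1) + (1 - alpha) * W Shat^(t-1)`,
#' which has no anchor and drifts to per-component consensus; it is provided
#' for finite-iteration experiments.  With `max_iter = 1` both variants give
#' the weighted nearest-neighbor blend
#' `alpha * S_a + (1 - alpha) * sum w(a, a') S_{a'}`.
#'
#' Every iterate is a convex combination of probability vectors, so revised
#' columns remain on the simplex exactly.  Isolated nodes keep their input.
#'
#' @inheritParams qp_infer_column
#' @param tol convergence threshold on the maximum absolute entry change.
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with a warning.
#' @param variant `"anchored"` (default) or `"literal"`.
#' @return n x 4 matrix of revised probability vectors with attributes
#'   `iterations` (integer) and `converged` (logical).
#' @export
lpa_infer_column <- function(S_cols, graph, alpha, tol = 1e-8,
                             max_iter = 1000L, variant = c("anchored", "literal")) {
  .check_prob_rows(S_cols)
  stopifnot(inherits(graph, "similarity_graph"))
  variant <- match.arg(variant)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (!all(graph$nodes %in% rownames(S_cols)))
    stop("graph nodes must be a subset of the cores in S_cols")
  active <- unique(graph$edges$from)   # nodes with outgoing mass
  out <- S_cols
  attr(out, "iterations") <- 0L
  attr(out, "converged") <- TRUE
  if (alpha == 1 || length(active) == 0L) return(out)
  W <- weight_matrix(graph, nodes = rownames(S_cols))
  act <- rownames(S_cols) %in% active
  S0 <- S_cols
  X <- S_cols
  converged <- FALSE
  iters <- 0L
  for (t in seq_len(max_iter)) {
    prop <- W %*% X
    Xn <- if (variant == "anchored") alpha * S0 + (1 - alpha) * prop
          else                       alpha * X  + (1 - alpha) * prop
    Xn[!act, ] <- X[!act, ]          # isolated nodes keep their input
    iters <- t
    delta <- max(abs(Xn - X))
    X <- Xn
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("label propagation did not converge in %d iterations (last max change above %.2g)",
                    max_iter, tol))
  out <- X
  rownames(out) <- rownames(S_cols)
  attr(out, "iterations") <- iters
  attr(out, "converged") <- converged
  out
}
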