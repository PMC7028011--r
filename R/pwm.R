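#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

#' Validate a position weight matrix
#'
#' A PWM is a 4 x k numeric matrix (rows A, C, G, T in that fixed order,
#' columns 5' to 3' binding-site positions) whose entries lie in \[0, 1\] and
#' whose columns each sum to 1.
#'
#' @param x numeric matrix to check.
#' @param tol numeric tolerance on the column-sum and range checks.
#' @return `x`, invisibly, with rownames set to A/C/G/T; errors if invalid.
#' @export
validate_pwm <- function(x, tol = 1e-9) {
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) != 4L || ncol(x) < 1L)
    stop("a PWM must be a numeric 4 x k matrix with k >= 1")
  if (any(!is.finite(x)))
    stop("PWM contains non-finite entries")
  if (any(x < -tol) || any(x > 1 + tol))
    stop("PWM entries must lie in [0, 1]")
  cs <- colSums(x)
  if (any(abs(cs - 1) > tol))
    stop(sprintf("PWM column(s) %s do not sum to 1",
                 paste(which(abs(cs - 1) > tol), collapse = ", ")))
  rownames(x) <- BASES
  invisible(x)
}

#' Validate a count matrix
#'
#' A count matrix is a 4 x k matrix of nonnegative reals (observed base
#' counts per binding-site position).
#'
#' @param x numeric matrix to check.
#' @return `x`, invisibly, with rownames set; errors if invalid.
#' @export
validate_counts <- function(x) {
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) != 4L || ncol(x) < 1L)
    stop("a count matrix must be a numeric 4 x k matrix with k >= 1")
  if (any(!is.finite(x)) || any(x < 0))
    stop("count matrix entries must be finite and >= 0")
  rownames(x) <- BASES
  invisible(x)
}

#' Convert a count matrix to a PWM
#'
#' Maximum-likelihood (optionally pseudocount-regularized) column-wise
#' normalization: entry (b, j) becomes
#' `(C[b,j] + pseudocount) / (sum_b' C[b',j] + 4 * pseudocount)`.
#'
#' @param C 4 x k count matrix.
#' @param pseudocount nonnegative real added to every cell before
#'   normalization.  Default 0: user-supplied PWMs arrive already estimated,
#'   so pseudocounts apply only on this count-to-frequency path.
#' @return a 4 x k PWM.
#' @examples
#' normalize_counts(matrix(c(3, 1, 0, 0), 4, 1), pseudocount = 1)
#' @export
normalize_counts <- function(C, pseudocount = 0) {
  validate_counts(C)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a single nonnegative number")
  tot <- colSums(C) + 4 * pseudocount
  if (any(tot <= 0))
    stop(sprintf("column(s) %s have zero total count and pseudocount = 0",
                 paste(which(tot <= 0), collapse = ", ")))
  P <- sweep(C + pseudocount, 2, tot, "/")
  rownames(P) <- BASES
  P
}

#' Aggregate several PWMs that share one core sequence
#'
#' DBD instances identical at all base-contacting positions are treated as a
#' single entity; their individually estimated PWMs are merged by an
#' unweighted entrywise mean (columns renormalized to absorb float error).
#' Count matrices, where available, should instead be summed and then passed
#' through [normalize_counts()].
#'
#' @param pwms nonempty list of 4 x k PWMs with a common k.
#' @return the aggregated 4 x k PWM.
#' @export
aggregate_by_core <- function(pwms) {
  if (!is.list(pwms) || length(pwms) == 0L)
    stop("pwms must be a nonempty list of PWMs")
  ks <- vapply(pwms, ncol, integer(1))
  if (length(unique(ks)) != 1L)
    stop("all PWMs must share the same number of columns")
  for (p in pwms) validate_pwm(p)
  m <- Reduce("+", pwms) / length(pwms)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- BASES
  m
}

#' Per-column information content of a PWM
#'
#' Relative entropy (bits) of each column against a background distribution:
#' `sum_b P[b,j] * log2(P[b,j] / bg[b])` with the convention 0 * log 0 = 0.
#' Under the default uniform background each column's value lies in \[0, 2\]
#' and is 0 iff the column is uniform.
#'
#' @param P a 4 x k PWM.
#' @param background strictly positive base probabilities summing to 1.
#' @return numeric k-vector of bits.
#' @export
information_content <- function(P, background = rep(0.25, 4)) {
  validate_pwm(P)
  if (!is.numeric(background) || length(background) != 4L ||
      any(background <= 0) || abs(sum(background) - 1) > 1e-9)
    stop("background must be 4 strictly positive probabilities summing to 1")
  apply(P, 2, function(p) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / background[nz]))
  })
}

#' Construct a dataset of PWMs keyed by core sequence
#'
#' A core sequence is the concatenation of a DBD instance's base-contacting
#' amino acids (four residues for single C2H2 zinc fingers); it is the unit
#' at which PWMs are aggregated and smoothed.
#'
#' @param pwms named list of 4 x k PWMs; names are the core sequences
#'   (uppercase single-letter amino-acid codes, all the same length) and must
#'   be unique.
#' @param label free-text dataset label.
#' @return an object of class `pwm_dataset` with fields `pwms`, `k`, `label`.
#' @export
pwm_dataset <- function(pwms, label = "") {
  if (!is.list(pwms) || length(pwms) == 0L)
    stop("pwms must be a nonempty named list")
  cores <- names(pwms)
  if (is.null(cores) || any(!nzchar(cores)))
    stop("every PWM must be named by its core sequence")
  if (anyDuplicated(cores))
    stop("duplicate core sequences; aggregate with aggregate_by_core() first")
  if (any(!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", cores)))
    stop("core sequences must be uppercase single-letter amino-acid codes")
  if (length(unique(nchar(cores))) != 1L)
    stop("all core sequences must have the same length")
  ks <- vapply(pwms, ncol, integer(1))
  if (length(unique(ks)) != 1L)
    stop("all PWMs in a dataset must share the same binding-site length k")
  pwms <- lapply(pwms, function(p) { validate_pwm(p); rownames(p) <- BASES; p })
  structure(list(pwms = pwms, k = ks[[1]], label = label),
            class = "pwm_dataset")
}

#' @export
print.pwm_dataset <- function(x, ...) {
  cat(sprintf("PWM dataset%s: %d core sequences, k = %d\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$pwms), x$k))
  invisible(x)
}

#' @export
`[.pwm_dataset` <- function(x, i) {
  pwm_dataset(x$pwms[i], label = x$label)
}

#' @export
length.pwm_dataset <- function(x) length(x$pwms)

#' Core sequences of a PWM dataset
#' @param dataset a `pwm_dataset`.
#' @return character vector of core sequences.
#' @export
cores <- function(dataset) names(dataset$pwms)
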