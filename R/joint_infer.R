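#' Jointly infer DNA-binding specificities across a PWM dataset
#'
#' The main fitting function.  Each binding-site position j is revised
#' independently: the j-th columns of all PWMs are coupled through the
#' similarity graph G_j and smoothed either by the constrained quadratic
#' program ([qp_infer_column()]) or by label-propagation adsorption
#' ([lpa_infer_column()]).  A single parameter `alpha` in (0, 1\] balances
#' fidelity to each core's initial estimate against dataset-wide
#' consistency: `alpha = 1` returns the input unchanged, and smaller values
#' pull cores with similar structural interfaces toward shared columns.
#'
#' @param dataset a [pwm_dataset()] of initial specificities S_a.
#' @param graphs list of [similarity_graph()], one per binding-site
#'   position, typically from [build_graphs()].
#' @param alpha fidelity parameter in (0, 1\].
#' @param method `"qp"` (constrained quadratic program, default) or `"lpa"`
#'   (label propagation).
#' @param positions binding-site positions to revise (default all); columns
#'   at other positions are copied unchanged, supporting protocols that
#'   smooth only selected positions.
#' @param lpa_variant,lpa_tol,lpa_max_iter label-propagation controls, see
#'   [lpa_infer_column()].
#' @param qp_feasibility_tol see [qp_infer_column()].
#' @return an object of class `joint_infer` with components
#'   \describe{
#'     \item{revised}{`pwm_dataset` of revised specificities Shat_a;}
#'     \item{initial}{the input dataset;}
#'     \item{diagnostics}{per-position solver status (LPA iteration counts
#'       and convergence, or `"exact"` for the QP solve);}
#'     \item{config}{the resolved settings, including `alpha` and `method`.}
#'   }
#' @examples
#' model <- contact_model(matrix(c(0.9, 0.05, 0.2, 0.95), 2, 2))
#' d <- pwm_dataset(list(
#'   AK = matrix(c(1, 0, 0, 0, 0.5, 0.5, 0, 0), 4, 2),
#'   AR = matrix(c(0, 1, 0, 0, 0.5, 0.5, 0, 0), 4, 2)))
#' g <- build_graphs(cores(d), model)
#' fit <- joint_infer(d, g, alpha = 0.5)
#' coef(fit)$AK
#' @export
joint_infer <- function(dataset, graphs, alpha = 0.4,
                        method = c("qp", "lpa"), positions = NULL,
                        lpa_variant = c("anchored", "literal"),
                        lpa_tol = 1e-8, lpa_max_iter = 1000L,
                        qp_feasibility_tol = 1e-9) {
  stopifnot(inherits(dataset, "pwm_dataset"))
  method <- match.arg(method)
  lpa_variant <- match.arg(lpa_variant)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  k <- dataset$k
  gj <- vapply(graphs, function(g) g$j, integer(1))
  if (any(gj < 1L | gj > k)) stop("graph positions must lie within 1..k")
  if (is.null(positions)) positions <- gj
  positions <- as.integer(positions)
  if (any(!(positions %in% gj)))
    stop("no similarity graph supplied for some requested position")
  cs <- cores(dataset)
  diagnostics <- vector("list", k)
  names(diagnostics) <- paste0("position_", seq_len(k))
  revised <- dataset$pwms
  for (j in positions) {
    S_cols <- t(vapply(dataset$pwms, function(p) p[, j], numeric(4)))
    rownames(S_cols) <- cs
    graph <- graphs[[match(j, gj)]]
    res <- tryCatch({
      if (method == "qp")
        qp_infer_column(S_cols, graph, alpha,
                        feasibility_tol = qp_feasibility_tol)
      else
        lpa_infer_column(S_cols, graph, alpha, tol = lpa_tol,
                         max_iter = lpa_max_iter, variant = lpa_variant)
    }, error = function(e) {
      stop(sprintf("position %d: %s", j, conditionMessage(e)), call. = FALSE)
    })
    diagnostics[[j]] <- if (method == "qp") list(status = "exact")
      else list(status = if (isTRUE(attr(res, "converged"))) "converged" else "max_iter",
                iterations = attr(res, "iterations"))
    for (idx in seq_along(cs)) revised[[idx]][, j] <- res[idx, ]
  }
  structure(list(
    revised = pwm_dataset(revised, label = dataset$label),
    initial = dataset,
    diagnostics = diagnostics,
    config = list(alpha = alpha, method = method, positions = sort(unique(positions)),
                  lpa_variant = lpa_variant, lpa_tol = lpa_tol,
                  lpa_max_iter = lpa_max_iter,
                  qp_feasibility_tol = qp_feasibility_tol)),
    class = "joint_infer")
}

#' @export
print.joint_infer <- function(x, ...) {
  cat(sprintf("Joint PWM inference (%s, alpha = %g)\n",
              toupper(x$config$method), x$config$alpha))
  cat(sprintf("  %d cores, k = %d, revised positions: %s\n",
              length(x$revised$pwms), x$revised$k,
              paste(x$config$positions, collapse = ", ")))
  invisible(x)
}

#' @export
summary.joint_infer <- function(object, ...) {
  ch <- vapply(seq_along(object$revised$pwms), function(i)
    max(abs(object$revised$pwms[[i]] - object$initial$pwms[[i]])), numeric(1))
  out <- list(config = object$config,
              n_cores = length(object$revised$pwms),
              max_change = stats::setNames(ch, cores(object$revised)),
              diagnostics = object$diagnostics)
  class(out) <- "summary.joint_infer"
  out
}

#' @export
print.summary.joint_infer <- function(x, ...) {
  cat(sprintf("Joint PWM inference (%s, alpha = %g), %d cores\n",
              toupper(x$config$method), x$config$alpha, x$n_cores))
  cat("Per-core max absolute entry change:\n")
  print(summary(x$max_change))
  for (nm in names(x$diagnostics)) {
    d <- x$diagnostics[[nm]]
    if (!is.null(d))
      cat(sprintf("  %s: %s%s\n", nm, d$status,
                  if (!is.null(d$iterations)) sprintf(" (%d iterations)", d$iterations) else ""))
  }
  invisible(x)
}

#' @export
coef.joint_infer <- function(object, ...) object$revised$pwms

#' @export
fitted.joint_infer <- function(object, ...) object$revised

#' @export
residuals.joint_infer <- function(object, ...) {
  mapply(function(r, s) r - s, object$revised$pwms, object$initial$pwms,
         SIMPLIFY = FALSE)
}

#' @export
plot.joint_infer <- function(x, ...) {
  ch <- vapply(seq_along(x$revised$pwms), function(i)
    max(abs(x$revised$pwms[[i]] - x$initial$pwms[[i]])), numeric(1))
  graphics::hist(ch, breaks = 30,
                 main = sprintf("Revision magnitude (%s, alpha = %g)",
                                toupper(x$config$method), x$config$alpha),
                 xlab = "max absolute entry change per core")
  invisible(x)
}
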