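# Agreement statistics between PWM datasets: per-column Pearson correlation,
# the >= 0.5 agreement rule, across-dataset agreement with a random-pairing
# control, agreement gain/loss enrichment, and Jaccard overlap of agreement
# sets.  PCC is used because it is insensitive to information content, which
# both differs between datasets and is changed by smoothing.

#' Pearson correlation between two PWM columns
#'
#' Standard Pearson correlation of the two probability 4-vectors.  Undefined
#' (returned as `NA`) when either vector has zero variance, i.e. is the
#' uniform column — undefined is a value here, not an error.
#'
#' @param u,v probability 4-vectors.
#' @return correlation in \[-1, 1\], or `NA` if undefined.
#' @export
column_pcc <- function(u, v) {
  if (length(u) != 4L || length(v) != 4L) stop("columns must be 4-vectors")
  du <- u - mean(u); dv <- v - mean(v)
  su <- sum(du^2); sv <- sum(dv^2)
  if (su == 0 || sv == 0) return(NA_real_)
  sum(du * dv) / sqrt(su * sv)
}

#' Do two PWM columns agree?
#'
#' Agreement means a defined Pearson correlation at or above the threshold
#' (default 0.5, inclusive).  The threshold is exposed so robustness to its
#' choice can be checked.
#'
#' @inheritParams column_pcc
#' @param threshold agreement threshold on the PCC (default 0.5).
#' @return logical; `FALSE` when the PCC is undefined.
#' @export
columns_agree <- function(u, v, threshold = 0.5) {
  r <- column_pcc(u, v)
  !is.na(r) && r >= threshold
}

# Three-way pair status.  Undefined-PCC pairs are excluded from agreement
# fractions, except that two columns equal entrywise within 1e-9 (e.g. both
# uniform) are unambiguous agreement.
.pair_status <- function(u, v, threshold = 0.5) {
  r <- column_pcc(u, v)
  if (is.na(r)) {
    if (max(abs(u - v)) <= 1e-9) "agree" else "undefined"
  } else if (r >= threshold) "agree" else "disagree"
}

# Assemble the (core, j) column pairs for two datasets under a pairing.
.column_pairs <- function(d1, d2, pairing = c("corresponding", "random"),
                          seed = NULL, positions = NULL) {
  pairing <- match.arg(pairing)
  shared <- intersect(cores(d1), cores(d2))
  if (length(shared) == 0L) stop("datasets share no core sequences")
  if (is.null(positions)) positions <- seq_len(min(d1$k, d2$k))
  mate <- shared
  if (pairing == "random") {
    if (is.null(seed)) stop("random pairing requires a seed")
    set.seed(as.integer(seed))
    mate <- sample(shared)   # bijection over the shared-core list
  }
  data.frame(core = rep(shared, each = length(positions)),
             mate = rep(mate, each = length(positions)),
             j = rep(positions, times = length(shared)),
             stringsAsFactors = FALSE)
}

#' Across-dataset agreement between two PWM datasets
#'
#' Pairs the j-th columns of the two datasets' PWMs for every shared core
#' sequence (or, as a control, for a seeded random bijection between the
#' shared cores, which preserves the number of pairs) and reports the
#' fraction of pairs in agreement and the median PCC over defined pairs.
#'
#' @param d1,d2 [pwm_dataset()] objects with a nonempty core intersection.
#' @param pairing `"corresponding"` (default) or `"random"`.
#' @param seed integer seed, required for random pairing.
#' @param positions binding-site positions to evaluate (default all shared).
#' @param threshold agreement threshold, see [columns_agree()].
#' @return an `agreement_report`: list with `fraction_agreeing`,
#'   `median_pcc`, `pairs` (one row per (core, j) with the PCC and status),
#'   `n_pairs`, `n_undefined_pcc`.
#' @export
across_dataset_agreement <- function(d1, d2,
                                     pairing = c("corresponding", "random"),
                                     seed = NULL, positions = NULL,
                                     threshold = 0.5) {
  pairing <- match.arg(pairing)
  pr <- .column_pairs(d1, d2, pairing, seed, positions)
  pcc <- numeric(nrow(pr)); status <- character(nrow(pr))
  for (i in seq_len(nrow(pr))) {
    u <- d1$pwms[[pr$core[i]]][, pr$j[i]]
    v <- d2$pwms[[pr$mate[i]]][, pr$j[i]]
    pcc[i] <- column_pcc(u, v)
    status[i] <- .pair_status(u, v, threshold)
  }
  defined <- status != "undefined"
  structure(list(
    fraction_agreeing = if (any(defined)) mean(status[defined] == "agree") else NA_real_,
    median_pcc = stats::median(pcc[!is.na(pcc)]),
    pairs = cbind(pr, pcc = pcc, status = status),
    n_pairs = nrow(pr),
    n_undefined_pcc = sum(!defined),
    pairing = pairing, threshold = threshold),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Across-dataset agreement (%s pairing, PCC >= %g):\n",
              x$pairing, x$threshold))
  cat(sprintf("  %d column pairs (%d undefined PCC)\n", x$n_pairs, x$n_undefined_pcc))
  cat(sprintf("  fraction agreeing: %.3f   median PCC: %.3f\n",
              x$fraction_agreeing, x$median_pcc))
  invisible(x)
}

#' Agreement set of an agreement report
#'
#' @param report an `agreement_report`.
#' @return character vector of `"core:j"` keys for the agreeing pairs.
#' @export
agreement_set <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  p <- report$pairs
  paste0(p$core[p$status == "agree"], ":", p$j[p$status == "agree"])
}

#' Agreement gain, loss and enrichment after joint inference
#'
#' Partitions the corresponding column pairs of two datasets into those
#' initially agreeing and those initially disagreeing (undefined-PCC pairs
#' excluded), then measures how the partition changes after revision:
#' `gain` is the fraction of initially disagreeing pairs that now agree,
#' `loss` the fraction of initially agreeing pairs that now disagree, and
#' `enrichment = gain / loss` (`NA` when a partition cell is empty or loss
#' is 0; enrichments computed from few pairs are unstable).
#'
#' @param initial_1,initial_2 initial datasets.
#' @param revised_1,revised_2 revised datasets over the same shared cores.
#' @param positions,threshold see [across_dataset_agreement()].
#' @return a `gain_loss_report`: list with `gain`, `loss`, `enrichment`,
#'   and the partition counts.
#' @export
gain_loss <- function(initial_1, initial_2, revised_1, revised_2,
                      positions = NULL, threshold = 0.5) {
  before <- across_dataset_agreement(initial_1, initial_2,
                                     positions = positions, threshold = threshold)
  after <- across_dataset_agreement(revised_1, revised_2,
                                    positions = positions, threshold = threshold)
  b <- before$pairs$status; a <- after$pairs$status
  if (!identical(paste(before$pairs$core, before$pairs$j),
                 paste(after$pairs$core, after$pairs$j)))
    stop("initial and revised datasets must induce the same column pairs")
  init_agree <- b == "agree"; init_dis <- b == "disagree"
  n_gain <- sum(init_dis & a == "agree")
  n_loss <- sum(init_agree & a == "disagree")
  gain <- if (any(init_dis)) n_gain / sum(init_dis) else NA_real_
  loss <- if (any(init_agree)) n_loss / sum(init_agree) else NA_real_
  enrichment <- if (!is.na(gain) && !is.na(loss) && loss > 0) gain / loss else NA_real_
  structure(list(gain = gain, loss = loss, enrichment = enrichment,
                 n_initially_disagreeing = sum(init_dis),
                 n_initially_agreeing = sum(init_agree),
                 n_gained = n_gain, n_lost = n_loss,
                 threshold = threshold),
            class = "gain_loss_report")
}

#' @export
print.gain_loss_report <- function(x, ...) {
  cat(sprintf("Agreement gain %.1f%% (%d/%d), loss %.1f%% (%d/%d), enrichment %s\n",
              100 * x$gain, x$n_gained, x$n_initially_disagreeing,
              100 * x$loss, x$n_lost, x$n_initially_agreeing,
              if (is.na(x$enrichment)) "undefined" else sprintf("%.1f-fold", x$enrichment)))
  invisible(x)
}

#' Jaccard overlap of two agreement sets
#'
#' `|A intersect B| / |A union B|` over (core, position) keys; two empty
#' sets overlap perfectly by convention (reported via a message).
#'
#' @param agree_set_A,agree_set_B character vectors of `"core:j"` keys, as
#'   produced by [agreement_set()].
#' @return Jaccard coefficient in \[0, 1\].
#' @export
jaccard_agreement_overlap <- function(agree_set_A, agree_set_B) {
  A <- unique(agree_set_A); B <- unique(agree_set_B)
  if (length(A) == 0L && length(B) == 0L) {
    message("both agreement sets empty; Jaccard overlap defined as 1")
    return(1)
  }
  length(intersect(A, B)) / length(union(A, B))
}

#' Agreement delta against an external reference dataset
#'
#' How much better the revised specificities agree with an independent
#' external dataset than the initial ones did, over the shared cores:
#' `delta = fraction(revised vs external) - fraction(initial vs external)`.
#' A seeded control repeats both comparisons against randomly drawn columns
#' of the external set (same number of pairs), where no improvement is
#' expected.
#'
#' @param revised,initial datasets over a common core set.
#' @param external the reference dataset; its core overlap with
#'   `initial`/`revised` must be nonempty.
#' @param positions,threshold see [across_dataset_agreement()].
#' @param seed integer seed for the random-column control.
#' @return list with `fraction_initial`, `fraction_revised`, `delta`,
#'   `fraction_initial_random`, `fraction_revised_random`, `delta_random`,
#'   `n_shared_cores`.
#' @export
external_comparison <- function(revised, external, initial,
                                positions = NULL, threshold = 0.5, seed = 1L) {
  fi <- across_dataset_agreement(initial, external,
                                 positions = positions, threshold = threshold)
  fr <- across_dataset_agreement(revised, external,
                                 positions = positions, threshold = threshold)
  fi_r <- across_dataset_agreement(initial, external, pairing = "random",
                                   seed = seed, positions = positions,
                                   threshold = threshold)
  fr_r <- across_dataset_agreement(revised, external, pairing = "random",
                                   seed = seed, positions = positions,
                                   threshold = threshold)
  list(fraction_initial = fi$fraction_agreeing,
       fraction_revised = fr$fraction_agreeing,
       delta = fr$fraction_agreeing - fi$fraction_agreeing,
       fraction_initial_random = fi_r$fraction_agreeing,
       fraction_revised_random = fr_r$fraction_agreeing,
       delta_random = fr_r$fraction_agreeing - fi_r$fraction_agreeing,
       n_shared_cores = length(intersect(cores(initial), cores(external))))
}
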