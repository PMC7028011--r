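# Synthetic replicate-dataset generator.  Emulates the statistical structure
# the smoothing method assumes in the C2H2 zinc-finger setting: clusters of
# core sequences whose specificity at each binding-site position is governed
# by one key contacting residue, observed twice with independent,
# heterogeneous noise (most cores near-truth, a fraction near-background, as
# when a high-throughput experiment fails for some proteins).

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), ncol = length(alpha),
              byrow = TRUE)
  x / rowSums(x)
}

#' Configuration of a synthetic world
#'
#' Defaults are the package's reference study conditions: 200 cores of four
#' contacting residues over a binding site of length 3 (the single-C2H2-ZF
#' geometry), ground-truth columns drawn from a sparse Dirichlet
#' (concentration 0.5, i.e. informative motif-like columns), two replicate
#' observations of 50 pseudo-sites per column, and a 20 percent
#' failed-experiment rate per dataset.
#'
#' @param n_cores number of distinct core sequences.
#' @param k binding-site length.
#' @param n_contacting number of base-contacting DBD positions (>= k).
#' @param alphabet_per_position list of `n_contacting` character vectors of
#'   residues available at each contacting position; default 8 residues per
#'   position.
#' @param truth_concentration Dirichlet concentration of ground-truth
#'   columns (smaller = sharper specificity).
#' @param noise_effective_counts pseudo-sites sampled per observed column;
#'   scalar, or one value per core for heterogeneous depth.
#' @param failure_rate fraction of cores per dataset whose observed PWM is
#'   replaced by a flat-Dirichlet draw (a failed experiment); in \[0, 1).
#' @param secondary_jitter optional mixing weight in \[0, 1\] perturbing each
#'   core's truth columns in proportion to the secondary contact frequency;
#'   0 (default) keeps truth sharing within key-residue groups exact.
#' @param seed integer seed; everything downstream is deterministic given it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_cores = 200L, k = 3L, n_contacting = 4L,
                             alphabet_per_position = NULL,
                             truth_concentration = 0.5,
                             noise_effective_counts = 50,
                             failure_rate = 0.2,
                             secondary_jitter = 0,
                             seed = 1L) {
  if (n_contacting < k) stop("n_contacting must be >= k")
  if (is.null(alphabet_per_position))
    alphabet_per_position <- rep(list(c("A", "D", "E", "H", "K", "N", "R", "S")),
                                 n_contacting)
  if (length(alphabet_per_position) != n_contacting)
    stop("alphabet_per_position must have one vector per contacting position")
  if (failure_rate < 0 || failure_rate >= 1) stop("failure_rate must lie in [0, 1)")
  if (any(noise_effective_counts <= 0)) stop("noise_effective_counts must be > 0")
  if (!length(noise_effective_counts) %in% c(1L, n_cores))
    stop("noise_effective_counts must be scalar or one value per core")
  structure(list(n_cores = as.integer(n_cores), k = as.integer(k),
                 n_contacting = as.integer(n_contacting),
                 alphabet_per_position = alphabet_per_position,
                 truth_concentration = truth_concentration,
                 noise_effective_counts = noise_effective_counts,
                 failure_rate = failure_rate,
                 secondary_jitter = secondary_jitter,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Contact model with one dominant key residue per binding-site position
# (contact frequency ~0.9), at most one secondary contacting residue per
# position (~0.2-0.4), and two non-contacting flanking DBD positions
# (<0.05, below the 10 percent calling threshold).  Keys run antiparallel
# (last contacting residue specifies position 1), mirroring the C2H2-ZF
# recognition geometry.
.synthetic_contact_model <- function(config) {
  p <- config$n_contacting; k <- config$k
  n_dbd <- p + 2L
  bc_rows <- seq(2L, p + 1L)          # contacting DBD positions
  M <- matrix(stats::runif(n_dbd * k, 0, 0.05), n_dbd, k)
  key_idx <- p + 1L - seq_len(k)      # index into bc_rows for each j
  for (j in seq_len(k))
    M[bc_rows[key_idx[j]], j] <- 0.9 + stats::runif(1, -0.03, 0.03)
  spares <- setdiff(seq_len(p), key_idx)
  if (length(spares) > 0L) {
    # each spare residue weakly contacts one binding-site position
    for (s in seq_along(spares)) {
      j <- k - ((s - 1L) %% k)
      M[bc_rows[spares[s]], j] <- stats::runif(1, 0.2, 0.4)
    }
  } else {
    for (j in seq(2L, length.out = max(0L, k - 1L)))
      M[bc_rows[key_idx[j - 1L]], j] <- stats::runif(1, 0.2, 0.4)
  }
  contact_model(M)
}

.sample_cores <- function(config) {
  sizes <- lengths(config$alphabet_per_position)
  space <- prod(sizes)
  if (space < config$n_cores)
    stop(sprintf("alphabets admit only %d distinct cores, %d requested",
                 space, config$n_cores))
  idx <- sample.int(space, config$n_cores)
  res <- matrix("", config$n_cores, config$n_contacting)
  rem <- idx - 1L
  for (l in seq_len(config$n_contacting)) {
    res[, l] <- config$alphabet_per_position[[l]][(rem %% sizes[l]) + 1L]
    rem <- rem %/% sizes[l]
  }
  apply(res, 1, paste0, collapse = "")
}

#' Generate a synthetic world of paired replicate PWM datasets
#'
#' Builds, deterministically from the seed: (1) a contact model with one
#' dominant key residue per binding-site position; (2) `n_cores` distinct
#' core sequences; (3) a ground-truth specificity per core in which cores
#' sharing the residue at position j's key position share j's truth column
#' exactly (one Dirichlet draw per (key residue, j) combination); (4) two
#' independent observed datasets, each column a multinomial resample of the
#' truth at `noise_effective_counts` pseudo-sites; (5) per dataset, a
#' `failure_rate` fraction of cores whose observed PWM is replaced by flat
#' Dirichlet draws.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_world`: list with `contact_model`, `cores`, `truth`,
#'   `dataset_1`, `dataset_2`, `failed_cores_1`, `failed_cores_2`, `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  model <- .synthetic_contact_model(config)
  core_seqs <- .sample_cores(config)
  k <- config$k
  bc <- model$base_contacting
  key_idx <- match(model$key_position, bc)   # contacting index keying each j
  sec_idx <- lapply(seq_len(k), function(j) {
    i <- setdiff(which(model$M[bc, j] >= model$contact_threshold), key_idx[j])
    if (length(i)) i[1] else NA_integer_
  })

  # one truth column per (key residue, j)
  truth_cols <- vector("list", k)
  for (j in seq_len(k)) {
    ab <- config$alphabet_per_position[[key_idx[j]]]
    draws <- .rdirichlet(length(ab), rep(config$truth_concentration, 4))
    truth_cols[[j]] <- stats::setNames(split(draws, row(draws)), ab)
  }
  res_mat <- do.call(rbind, strsplit(core_seqs, ""))
  truth <- lapply(seq_along(core_seqs), function(i) {
    P <- vapply(seq_len(k), function(j) {
      col <- truth_cols[[j]][[res_mat[i, key_idx[j]]]]
      sj <- config$secondary_jitter
      if (sj > 0 && !is.na(sec_idx[[j]])) {
        wmix <- sj * model$M[bc[sec_idx[[j]]], j]
        col <- (1 - wmix) * col + wmix * as.numeric(.rdirichlet(1, rep(1, 4)))
      }
      col
    }, numeric(4))
    rownames(P) <- BASES
    P
  })
  names(truth) <- core_seqs
  truth_ds <- pwm_dataset(truth, label = "truth")

  depth <- rep(round(config$noise_effective_counts), length.out = config$n_cores)
  depth <- pmax(depth, 1)
  n_fail <- round(config$failure_rate * config$n_cores)
  observe <- function(label) {
    obs <- lapply(seq_along(core_seqs), function(i) {
      P <- vapply(seq_len(k), function(j)
        as.numeric(stats::rmultinom(1, depth[i], truth[[i]][, j])) / depth[i],
        numeric(4))
      rownames(P) <- BASES
      P
    })
    names(obs) <- core_seqs
    failed <- if (n_fail > 0L) sort(sample(core_seqs, n_fail)) else character(0)
    for (f in failed) {
      P <- t(.rdirichlet(k, rep(1, 4)))
      rownames(P) <- BASES
      obs[[f]] <- P
    }
    list(dataset = pwm_dataset(obs, label = label), failed = failed)
  }
  o1 <- observe("replicate_1")
  o2 <- observe("replicate_2")
  structure(list(contact_model = model, cores = core_seqs, truth = truth_ds,
                 dataset_1 = o1$dataset, dataset_2 = o2$dataset,
                 failed_cores_1 = o1$failed, failed_cores_2 = o2$failed,
                 config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("Synthetic world: %d cores, k = %d, %d contacting positions (seed %d)\n",
              x$config$n_cores, x$config$k, x$config$n_contacting, x$config$seed))
  cat(sprintf("  failed experiments: %d (replicate 1), %d (replicate 2)\n",
              length(x$failed_cores_1), length(x$failed_cores_2)))
  invisible(x)
}

# Mean per-column distance to truth over a set of cores.
.distance_to_truth <- function(dataset, truth, which_cores) {
  if (length(which_cores) == 0L)
    return(c(one_minus_pcc = NA_real_, l1 = NA_real_, n = 0))
  omp <- c(); l1 <- c()
  for (cs in which_cores) {
    for (j in seq_len(truth$k)) {
      u <- dataset$pwms[[cs]][, j]; v <- truth$pwms[[cs]][, j]
      r <- column_pcc(u, v)
      if (!is.na(r)) omp <- c(omp, 1 - r)
      l1 <- c(l1, sum(abs(u - v)))
    }
  }
  c(one_minus_pcc = mean(omp), l1 = mean(l1), n = length(l1))
}

#' Recovery metrics of joint inference on a synthetic world
#'
#' Quantifies how far each replicate dataset moved toward the planted ground
#' truth: mean per-column distance to truth (1 - PCC, and L1), separately
#' for failed and non-failed cores, before and after revision, plus the
#' across-dataset agreement fraction at both stages.
#'
#' @param world a [generate_world()] result.
#' @param revised_1,revised_2 revised datasets over the world's cores.
#' @param threshold agreement threshold, see [columns_agree()].
#' @return list with `distance` (data.frame: dataset, group, stage, metrics)
#'   and `agreement_before` / `agreement_after` fractions.
#' @export
recovery_metrics <- function(world, revised_1, revised_2, threshold = 0.5) {
  stopifnot(inherits(world, "synthetic_world"))
  rows <- list()
  stage_sets <- list(
    list(ds = world$dataset_1, name = "1", stage = "initial", failed = world$failed_cores_1),
    list(ds = revised_1,       name = "1", stage = "revised", failed = world$failed_cores_1),
    list(ds = world$dataset_2, name = "2", stage = "initial", failed = world$failed_cores_2),
    list(ds = revised_2,       name = "2", stage = "revised", failed = world$failed_cores_2))
  for (s in stage_sets) {
    ok <- setdiff(world$cores, s$failed)
    for (grp in c("failed", "ok")) {
      m <- .distance_to_truth(s$ds, world$truth,
                              if (grp == "failed") s$failed else ok)
      rows[[length(rows) + 1L]] <-
        data.frame(dataset = s$name, group = grp, stage = s$stage,
                   mean_one_minus_pcc = m[["one_minus_pcc"]],
                   mean_l1 = m[["l1"]], n_columns = m[["n"]],
                   stringsAsFactors = FALSE)
    }
  }
  list(distance = do.call(rbind, rows),
       agreement_before = across_dataset_agreement(
         world$dataset_1, world$dataset_2, threshold = threshold)$fraction_agreeing,
       agreement_after = across_dataset_agreement(
         revised_1, revised_2, threshold = threshold)$fraction_agreeing)
}
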