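#' Construct a contact instance
#'
#' One aligned DBD-DNA co-complex observation: an aligned DBD amino-acid
#' sequence plus a boolean contact map whose (i, j) entry is TRUE iff some
#' non-hydrogen atom of residue i lies within the contact distance
#' (conventionally 3.6 angstroms) of a base at binding-site position j.
#' Structural alignment and distance calling happen upstream; this package
#' consumes the aligned maps.
#'
#' @param dbd_sequence amino-acid string over the aligned DBD positions.
#' @param contacts logical matrix, aligned DBD length x k.
#' @return an object of class `contact_instance`.
#' @export
contact_instance <- function(dbd_sequence, contacts) {
  if (!is.character(dbd_sequence) || length(dbd_sequence) != 1L)
    stop("dbd_sequence must be a single string")
  contacts <- as.matrix(contacts)
  storage.mode(contacts) <- "logical"
  if (nrow(contacts) != nchar(dbd_sequence))
    stop("contacts must have one row per aligned DBD position")
  structure(list(dbd_sequence = toupper(dbd_sequence), contacts = contacts),
            class = "contact_instance")
}

#' Contact-frequency interface model for a DBD family
#'
#' Wraps a contact-frequency matrix `M` (DBD position i x binding-site
#' position j, values in \[0, 1\]) and derives from it:
#' * `base_contacting`: DBD positions i with `max_j M[i, j] >= contact_threshold`
#'   (a residue counts as base-contacting if it touches a base in at least
#'   10 percent of co-complex instances, by default);
#' * `key_position`: for each j, the base-contacting position i maximizing
#'   `M[i, j]` (ties broken toward the lowest i; `NA` when no base-contacting
#'   position touches j, in which case all pair weights at j are zero).
#'
#' @param M numeric matrix of contact frequencies in \[0, 1\].
#' @param contact_threshold contact-calling threshold in (0, 1\], default 0.10.
#' @return an object of class `contact_model` with fields `M`,
#'   `contact_threshold`, `base_contacting`, `key_position`.
#' @export
contact_model <- function(M, contact_threshold = 0.10) {
  M <- as.matrix(M)
  if (!is.numeric(M) || any(!is.finite(M)) || any(M < 0) || any(M > 1))
    stop("M must be a numeric matrix with entries in [0, 1]")
  bc <- call_base_contacting(M, contact_threshold)
  k <- ncol(M)
  key <- rep(NA_integer_, k)
  if (length(bc) > 0L) {
    for (j in seq_len(k)) {
      col <- M[bc, j]
      if (any(col > 0))
        key[j] <- bc[which.max(col)]   # which.max takes the first (lowest i) on ties
    }
  }
  structure(list(M = M, contact_threshold = contact_threshold,
                 base_contacting = bc, key_position = key),
            class = "contact_model")
}

#' Call base-contacting DBD positions from a contact-frequency matrix
#'
#' A DBD position is base-contacting when it contacts a base in at least a
#' threshold fraction of co-complex instances at some binding-site position,
#' i.e. `max_j M[i, j] >= threshold` (inclusive).
#'
#' @param M contact-frequency matrix.
#' @param threshold calling threshold in (0, 1\].
#' @return ascending integer vector of base-contacting DBD positions.
#' @export
call_base_contacting <- function(M, threshold = 0.10) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  M <- as.matrix(M)
  which(apply(M, 1, max) >= threshold)
}

#' Key DBD position for a binding-site position
#'
#' The DBD position most frequently contacting binding-site position j,
#' restricted to base-contacting positions; a mismatch there voids the
#' similarity prior at j.
#'
#' @param model a `contact_model`.
#' @param j binding-site position (1-based).
#' @return integer DBD position.
#' @export
key_position <- function(model, j) {
  stopifnot(inherits(model, "contact_model"))
  if (j < 1L || j > ncol(model$M)) stop("j out of range")
  kp <- model$key_position[j]
  if (is.na(kp))
    stop(sprintf(paste0("no base-contacting DBD position contacts binding-site",
                        " position %d; pair weights at this position are 0"), j))
  kp
}

#' Compute a uniqueness-weighted contact-frequency matrix
#'
#' Each instance is down-weighted by the multiplicity of its aligned DBD
#' sequence (weight 1 / number of instances with an identical sequence), so
#' that redundant deposition of the same DBD across co-complex structures
#' does not inflate contact frequencies; duplicating every instance once
#' leaves M unchanged.  `M[i, j]` is then the weighted fraction of instances
#' whose residue i contacts a base at binding-site position j.
#'
#' @param instances nonempty list of [contact_instance()] objects sharing
#'   dimensions.
#' @param contact_threshold passed to [contact_model()].
#' @return a `contact_model`.
#' @export
compute_contact_frequency <- function(instances, contact_threshold = 0.10) {
  if (!is.list(instances) || length(instances) == 0L)
    stop("instances must be a nonempty list")
  for (x in instances)
    if (!inherits(x, "contact_instance")) stop("all elements must be contact_instance objects")
  dims <- vapply(instances, function(x) dim(x$contacts), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all contact maps must share dimensions")
  seqs <- vapply(instances, function(x) x$dbd_sequence, character(1))
  w <- 1 / table(seqs)[seqs]
  w <- as.numeric(w)
  acc <- matrix(0, dims[1, 1], dims[2, 1])
  for (idx in seq_along(instances))
    acc <- acc + w[idx] * instances[[idx]]$contacts
  contact_model(acc / sum(w), contact_threshold = contact_threshold)
}

#' @export
print.contact_model <- function(x, ...) {
  cat(sprintf("Contact model: %d aligned DBD positions x %d binding-site positions\n",
              nrow(x$M), ncol(x$M)))
  cat(sprintf("  base-contacting positions (threshold %.2f): %s\n",
              x$contact_threshold, paste(x$base_contacting, collapse = ", ")))
  cat(sprintf("  key position per binding-site position: %s\n",
              paste(x$key_position, collapse = ", ")))
  invisible(x)
}
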