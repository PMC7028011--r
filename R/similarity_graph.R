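#' Construct a per-position similarity graph
#'
#' One directed weighted graph G_j per binding-site position j: nodes are
#' core sequences, an edge (a, a') carries the normalized prior expectation
#' w_j(a, a') that a and a' share specificity at position j.  After
#' normalization each node's outgoing weights sum to 1; zero-weight pairs
#' are absent rather than stored.
#'
#' @param j binding-site position the graph describes.
#' @param nodes character vector of core sequences (includes isolated nodes).
#' @param edges data.frame with columns `from`, `to`, `weight` (weights
#'   strictly positive, no self-edges).
#' @param normalized logical; if TRUE (default) each node's outgoing weights
#'   must sum to 1 within `tol`.
#' @param tol tolerance for the normalization check.
#' @return an object of class `similarity_graph`.
#' @export
similarity_graph <- function(j, nodes, edges, normalized = TRUE, tol = 1e-9) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate nodes")
  if (nrow(edges) > 0L) {
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (any(edges$from == edges$to)) stop("self-edges are not allowed")
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0))
      stop("edge weights must be strictly positive")
    if (!all(edges$from %in% nodes) || !all(edges$to %in% nodes))
      stop("edge endpoints must be graph nodes")
    if (normalized) {
      s <- tapply(edges$weight, edges$from, sum)
      if (any(abs(s - 1) > tol))
        stop("outgoing weights must sum to 1 per node")
    }
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(j = as.integer(j), nodes = nodes,
                 edges = edges[c("from", "to", "weight")]),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  iso <- sum(!(x$nodes %in% x$edges$from))
  cat(sprintf("Similarity graph G_%d: %d nodes (%d isolated), %d directed edges\n",
              x$j, length(x$nodes), iso, nrow(x$edges)))
  invisible(x)
}

#' Dense out-weight matrix of a similarity graph
#'
#' Row a, column a' holds the normalized weight w_j(a, a'); isolated nodes
#' have all-zero rows.
#'
#' @param graph a `similarity_graph`.
#' @param nodes optional node ordering (default the graph's own).
#' @return numeric matrix with dimnames.
#' @export
weight_matrix <- function(graph, nodes = graph$nodes) {
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  e <- graph$edges
  if (nrow(e) > 0L)
    W[cbind(match(e$from, nodes), match(e$to, nodes))] <- e$weight
  W
}

# Map core-sequence character positions to contact-model columns: the l-th
# residue of a core sequence sits at the l-th base-contacting DBD position.
.core_contact_rows <- function(model) {
  bc <- model$base_contacting
  if (length(bc) == 0L) stop("contact model has no base-contacting positions")
  bc
}

#' Unnormalized pair weights across all binding-site positions
#'
#' For cores a and a' differing at the set D of base-contacting positions:
#' if |D| > `max_mismatch` there is no prior expectation of similarity and
#' the weight is 0 at every position.  Otherwise, at each binding-site
#' position j the weight is 0 when D contains j's key position, and
#' `prod_{i in D} (1 - M[i, j])` otherwise — for `max_mismatch = 1` exactly
#' the single-mismatch rule `1 - M[i, j]` for the one differing position i.
#'
#' @param a,a2 core sequences (distinct, length = number of base-contacting
#'   positions of `model`).
#' @param model a [contact_model()].
#' @param max_mismatch maximum number of differing base-contacting positions
#'   with a nonzero prior (1 for single C2H2 zinc fingers, up to 4 for
#'   Homeodomains).
#' @return numeric k-vector of unnormalized weights in \[0, 1\].
#' @export
pair_weights <- function(a, a2, model, max_mismatch = 1) {
  stopifnot(inherits(model, "contact_model"))
  if (identical(a, a2)) stop("pair weights are undefined for a core against itself")
  bc <- .core_contact_rows(model)
  if (nchar(a) != length(bc) || nchar(a2) != length(bc))
    stop("core length must equal the number of base-contacting positions")
  k <- ncol(model$M)
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(a2, "")[[1]]
  D <- which(ra != rb)
  if (length(D) > max_mismatch) return(rep(0, k))
  w <- numeric(k)
  for (j in seq_len(k)) {
    kp <- model$key_position[j]
    if (is.na(kp) || kp %in% bc[D]) {
      w[j] <- 0
    } else {
      w[j] <- prod(1 - model$M[bc[D], j])
    }
  }
  w
}

#' Build per-position similarity graphs over a set of cores
#'
#' Computes unnormalized pair weights for every pair of cores, keeps the
#' strictly positive ones as directed edges (both directions share the same
#' unnormalized weight), and normalizes each node's outgoing weights to sum
#' to 1 per position.  Nodes with no outgoing edge at a position stay
#' isolated there (no normalization applied).
#'
#' @param core_seqs character vector of unique core sequences.
#' @param model a [contact_model()].
#' @param max_mismatch see [pair_weights()].
#' @return list of `similarity_graph`, one per binding-site position.
#' @export
build_graphs <- function(core_seqs, model, max_mismatch = 1) {
  stopifnot(inherits(model, "contact_model"))
  core_seqs <- as.character(core_seqs)
  if (anyDuplicated(core_seqs)) stop("core sequences must be unique")
  bc <- .core_contact_rows(model)
  p <- length(bc)
  if (any(nchar(core_seqs) != p))
    stop("core length must equal the number of base-contacting positions")
  n <- length(core_seqs)
  k <- ncol(model$M)
  # residue matrix n x p, then per-position mismatch indicators
  R <- do.call(rbind, strsplit(core_seqs, ""))
  diff_l <- lapply(seq_len(p), function(l) outer(R[, l], R[, l], "!="))
  mism <- Reduce("+", diff_l)
  eligible <- mism > 0 & mism <= max_mismatch
  graphs <- vector("list", k)
  for (j in seq_len(k)) {
    kp <- model$key_position[j]
    # per-pair product of (1 - M[i, j]) over differing positions; a factor of
    # 0 at the key position annihilates the product, implementing the
    # key-mismatch rule
    Wu <- matrix(1, n, n)
    for (l in seq_len(p)) {
      f <- if (!is.na(kp) && bc[l] == kp) 0 else 1 - model$M[bc[l], j]
      if (f != 1) Wu <- Wu * ifelse(diff_l[[l]], f, 1)
    }
    Wu[!eligible] <- 0
    if (is.na(kp)) Wu[] <- 0
    rs <- rowSums(Wu)
    pos <- which(Wu > 0, arr.ind = TRUE)
    edges <- data.frame(from = core_seqs[pos[, 1]], to = core_seqs[pos[, 2]],
                        weight = Wu[pos] / rs[pos[, 1]],
                        stringsAsFactors = FALSE)
    graphs[[j]] <- similarity_graph(j, core_seqs, edges)
  }
  graphs
}

#' Drop cores that are isolated in every similarity graph
#'
#' A core with no outgoing edge at any binding-site position can receive no
#' information from the rest of the dataset; such cores are removed before
#' joint inference.
#'
#' @param dataset a [pwm_dataset()].
#' @param graphs list of `similarity_graph` built over the dataset's cores.
#' @return the restricted `pwm_dataset`; the number removed is messaged.
#' @export
filter_isolated <- function(dataset, graphs) {
  stopifnot(inherits(dataset, "pwm_dataset"))
  connected <- unique(unlist(lapply(graphs, function(g) unique(g$edges$from))))
  keep <- cores(dataset) %in% connected
  message(sprintf("filter_isolated: removed %d of %d cores with no similarity edge",
                  sum(!keep), length(keep)))
  if (!any(keep))
    return(structure(list(pwms = dataset$pwms[0], k = dataset$k,
                          label = dataset$label), class = "pwm_dataset"))
  dataset[keep]
}

#' Permute node identities within each similarity graph
#'
#' Randomization control: a random bijection over the node set is drawn
#' independently for each graph (or shared across graphs) and applied to
#' relabel edge endpoints.  The weight multiset and out-degree sequence are
#' preserved; only the correspondence between cores and graph neighborhoods
#' is destroyed.
#'
#' @param graphs list of `similarity_graph`.
#' @param seed integer seed; the permutations are deterministic given it.
#' @param share_permutation if TRUE, one bijection is drawn and applied to
#'   every graph; default FALSE (one independent bijection per graph).
#' @return list of relabeled `similarity_graph`.
#' @export
permute_nodes <- function(graphs, seed, share_permutation = FALSE) {
  set.seed(as.integer(seed))
  shared <- NULL
  lapply(graphs, function(g) {
    perm <- if (share_permutation) {
      if (is.null(shared)) shared <<- sample(g$nodes)
      shared
    } else sample(g$nodes)
    names(perm) <- g$nodes
    e <- g$edges
    if (nrow(e) > 0L) {
      e$from <- unname(perm[e$from])
      e$to <- unname(perm[e$to])
    }
    similarity_graph(g$j, g$nodes, e)
  })
}
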