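# Shared fixtures, built in code.

random_pwm <- function(k = 3, conc = 0.7) {
  m <- matrix(rgamma(4 * k, shape = conc), 4, k)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- c("A", "C", "G", "T")
  m
}

random_prob_rows <- function(n, conc = 0.7, names = sprintf("C%02d", seq_len(n))) {
  S <- matrix(rgamma(4 * n, shape = conc), n, 4)
  S <- S / rowSums(S)
  rownames(S) <- names
  S
}

random_pwm_dataset <- function(n = 5, k = 3, label = "fixture") {
  nm <- replicate(n, paste0(sample(c("A", "C", "D", "E", "F", "G", "H", "I"), 4, replace = TRUE), collapse = ""))
  while (anyDuplicated(nm))
    nm[duplicated(nm)] <- replicate(sum(duplicated(nm)),
                                    paste0(sample(c("A", "C", "D", "E", "F", "G", "H", "I"), 4, replace = TRUE), collapse = ""))
  pwm_dataset(setNames(lapply(seq_len(n), function(i) random_pwm(k)), nm), label = label)
}

mutual_graph <- function(nodes = c("AA", "RR")) {
  similarity_graph(1L, nodes,
                   data.frame(from = nodes, to = rev(nodes), weight = c(1, 1)))
}

# A small hand-set contact model: 4 contacting DBD positions (rows 1-4),
# k = 3; keys are rows 4, 3, 2 for positions 1, 2, 3; row 1 contacts only
# position 3 weakly.
toy_contact_model <- function() {
  M <- matrix(0, 4, 3)
  M[4, 1] <- 0.9
  M[3, 2] <- 0.85
  M[2, 3] <- 0.92
  M[1, 3] <- 0.30
  M[2, 1] <- 0.25
  contact_model(M)
}

# Random normalized directed graph in which every node has >= 1 outgoing
# edge (built on a random Hamiltonian cycle plus extra random edges).
random_graph <- function(nodes, j = 1L, extra = length(nodes)) {
  n <- length(nodes)
  ring <- sample(n)
  e <- data.frame(from = nodes[ring], to = nodes[c(ring[-1], ring[1])],
                  weight = runif(n, 0.2, 1), stringsAsFactors = FALSE)
  if (extra > 0 && n > 2) {
    fr <- sample(n, extra, replace = TRUE)
    to <- vapply(fr, function(i) sample(setdiff(seq_len(n), i), 1), integer(1))
    e <- rbind(e, data.frame(from = nodes[fr], to = nodes[to],
                             weight = runif(extra, 0.2, 1)))
    e <- e[!duplicated(e[c("from", "to")]), ]
  }
  s <- tapply(e$weight, e$from, sum)
  e$weight <- e$weight / s[e$from]
  similarity_graph(j, nodes, e)
}
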