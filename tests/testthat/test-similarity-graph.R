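test_that("pair weights reproduce the structural similarity rules", {
  model <- toy_contact_model()   # keys: j=1 -> DBD 4, j=2 -> DBD 3, j=3 -> DBD 2

  # more than max_mismatch differing contacting positions: no expectation
  expect_equal(pair_weights("AAAA", "AABB", model, max_mismatch = 1), c(0, 0, 0))

  # mismatch at j's key position voids the prior at that j; elsewhere the
  # single-mismatch weight is 1 - M[i, j]
  w <- pair_weights("AAAA", "AABA", model)   # differ at DBD position 3 (key of j=2)
  expect_equal(w[2], 0)
  expect_equal(w[1], 1 - model$M[3, 1])
  expect_equal(w[3], 1 - model$M[3, 3])

  w <- pair_weights("AAAA", "BAAA", model)   # differ at DBD position 1, M[1, 3] = 0.3
  expect_equal(w[3], 0.7)
  expect_equal(w[1], 1 - model$M[1, 1])

  expect_error(pair_weights("AAAA", "AAAA", model), "itself")
  expect_error(pair_weights("AAA", "AAB", model), "length")
})

test_that("pair weights are symmetric and multi-mismatch reduces to the product rule", {
  model <- toy_contact_model()
  set.seed(9)
  for (rep in 1:20) {
    a <- paste0(sample(c("A", "B", "C"), 4, replace = TRUE), collapse = "")
    b <- paste0(sample(c("A", "B", "C"), 4, replace = TRUE), collapse = "")
    if (a == b) next
    for (mm in 1:4)
      expect_equal(pair_weights(a, b, model, mm), pair_weights(b, a, model, mm))
    # with one mismatch, the product over differing positions is the single
    # printed factor
    ra <- strsplit(a, "")[[1]]; rb <- strsplit(b, "")[[1]]
    D <- which(ra != rb)
    if (length(D) == 1L) {
      w <- pair_weights(a, b, model, 1)
      for (j in 1:3) {
        expected <- if (model$base_contacting[D] == model$key_position[j]) 0
                    else 1 - model$M[model$base_contacting[D], j]
        expect_equal(w[j], expected)
      }
    }
  }
  # explicit multi-mismatch product: cores differing at DBD 1 and 4
  w <- pair_weights("AAAA", "BAAB", model, max_mismatch = 2)
  expect_equal(w[1], 0)                                    # DBD 4 is key of j=1
  expect_equal(w[3], (1 - model$M[1, 3]) * (1 - model$M[4, 3]))
})

test_that("graph construction normalizes outgoing weights per node", {
  # three contacting positions, key of each j is a different one; cores sit
  # so that node A has neighbors with unnormalized weights 0.6 and 0.2 at j=1
  M <- matrix(0, 3, 3)
  M[1, 1] <- 0.4; M[2, 1] <- 0.8; M[3, 1] <- 0.85
  M[2, 2] <- 0.9; M[1, 3] <- 0.05; M[3, 3] <- 0.9; M[1, 2] <- 0.05
  model <- contact_model(M)   # keys: j=1 -> 3, j=2 -> 2, j=3 -> 3
  graphs <- build_graphs(c("AAA", "BAA", "ABA"), model)
  e1 <- graphs[[1]]$edges
  wAB <- e1$weight[e1$from == "AAA" & e1$to == "BAA"]   # 1-M[1,1]=0.6 raw
  wAC <- e1$weight[e1$from == "AAA" & e1$to == "ABA"]   # 1-M[2,1]=0.2 raw
  expect_equal(wAB, 0.75)
  expect_equal(wAC, 0.25)
  # equal raw weights normalize to 0.5 each
  Meq <- matrix(0, 3, 3); Meq[1, 1] <- 0.3; Meq[2, 1] <- 0.3
  Meq[3, 1] <- 0.9; Meq[2, 2] <- 0.9; Meq[3, 3] <- 0.9; Meq[1, 2] <- 0.15
  geq <- build_graphs(c("AAA", "BAA", "ABA"), contact_model(Meq))
  eq1 <- geq[[1]]$edges
  expect_equal(eq1$weight[eq1$from == "AAA"], c(0.5, 0.5))

  # cores too far apart are isolated in every graph
  far <- build_graphs(c("AAAA", "BBBA"), toy_contact_model(), max_mismatch = 1)
  for (g in far) expect_equal(nrow(g$edges), 0L)

  set.seed(21)
  model4 <- toy_contact_model()
  for (rep in 1:10) {
    cs <- unique(replicate(12, paste0(sample(c("A", "B"), 4, TRUE), collapse = "")))
    graphs <- build_graphs(cs, model4, max_mismatch = sample(1:3, 1))
    for (g in graphs) {
      if (nrow(g$edges) == 0L) next
      sums <- tapply(g$edges$weight, g$edges$from, sum)
      expect_true(all(abs(sums - 1) < 1e-9))
      expect_true(all(g$edges$weight > 0))
      expect_true(all(g$edges$from != g$edges$to))
    }
  }
})

test_that("isolated cores are filtered out of a dataset", {
  model <- toy_contact_model()
  mk <- function(nms) pwm_dataset(setNames(lapply(nms, function(x) random_pwm()), nms))

  # fully connected pair stays, distant third core goes
  d3 <- mk(c("AAAA", "AAAD", "CCCC"))
  g3 <- build_graphs(cores(d3), model)
  expect_message(kept <- filter_isolated(d3, g3), "removed 1 of 3")
  expect_setequal(cores(kept), c("AAAA", "AAAD"))

  # pairwise >= 2 mismatches everywhere: everything removed
  dfar <- mk(c("AAAA", "DDAA", "CCAA"))
  gfar <- build_graphs(cores(dfar), model)
  expect_message(empty <- filter_isolated(dfar, gfar), "removed 3 of 3")
  expect_equal(length(empty), 0L)

  # clique unchanged
  dcl <- mk(c("AAAA", "AAAD", "AAAC"))
  gcl <- build_graphs(cores(dcl), model)
  expect_message(full <- filter_isolated(dcl, gcl), "removed 0 of 3")
  expect_setequal(cores(full), cores(dcl))
})

test_that("node permutation relabels but preserves weight structure", {
  set.seed(33)
  nodes <- sprintf("N%02d", 1:12)
  graphs <- list(random_graph(nodes, j = 1L), random_graph(nodes, j = 2L))
  perm <- permute_nodes(graphs, seed = 99)
  perm2 <- permute_nodes(graphs, seed = 99)
  for (i in 1:2) {
    expect_setequal(perm[[i]]$nodes, nodes)
    expect_equal(sort(perm[[i]]$edges$weight), sort(graphs[[i]]$edges$weight))
    expect_equal(sort(table(perm[[i]]$edges$from)), sort(table(graphs[[i]]$edges$from)),
                 ignore_attr = TRUE)
    sums <- tapply(perm[[i]]$edges$weight, perm[[i]]$edges$from, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_equal(perm[[i]]$edges, perm2[[i]]$edges)   # deterministic given seed
  }
  one <- similarity_graph(1L, "A", data.frame(from = character(0), to = character(0),
                                              weight = numeric(0)))
  expect_equal(permute_nodes(list(one), seed = 5)[[1]]$nodes, "A")
})
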