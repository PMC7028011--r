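onehot <- function(b) { v <- numeric(4); v[b] <- 1; v }

test_that("column PCC handles self, orthogonal and degenerate columns", {
  u <- c(0.7, 0.1, 0.1, 0.1)
  expect_equal(column_pcc(u, u), 1)
  expect_equal(column_pcc(onehot(1), onehot(2)), -1/3)
  expect_true(is.na(column_pcc(rep(0.25, 4), u)))
  # symmetry and affine invariance
  set.seed(30)
  for (rep in 1:10) {
    a <- runif(4); b <- runif(4)
    expect_equal(column_pcc(a, b), column_pcc(b, a))
    expect_equal(column_pcc(2 * a + 0.3, b), column_pcc(a, b), tolerance = 1e-12)
  }
})

test_that("agreement is inclusive at the threshold and undefined PCC never agrees", {
  u <- c(0.7, 0.1, 0.1, 0.1)
  expect_true(columns_agree(u, u))
  expect_false(columns_agree(onehot(1), onehot(2)))
  v <- c(0.5, 0.3, 0.1, 0.1)
  r <- column_pcc(u, v)
  expect_true(columns_agree(u, v, threshold = r))           # PCC == threshold
  expect_false(columns_agree(u, v, threshold = r + 1e-12))
  expect_false(columns_agree(rep(0.25, 4), u))
})

test_that("across-dataset agreement distinguishes identical, orthogonal and random pairings", {
  set.seed(31)
  d <- random_pwm_dataset(n = 6, k = 3)
  rep_same <- across_dataset_agreement(d, d)
  expect_equal(rep_same$fraction_agreeing, 1)
  expect_equal(rep_same$median_pcc, 1)
  expect_equal(rep_same$n_pairs, 18L)

  nms <- cores(d)[1:2]
  d1 <- pwm_dataset(setNames(list(cbind(onehot(1)), cbind(onehot(3))), nms))
  d2 <- pwm_dataset(setNames(list(cbind(onehot(2)), cbind(onehot(4))), nms))
  ortho <- across_dataset_agreement(d1, d2)
  expect_equal(ortho$fraction_agreeing, 0)
  expect_equal(ortho$median_pcc, -1/3)

  r1 <- across_dataset_agreement(d, d, pairing = "random", seed = 8)
  r2 <- across_dataset_agreement(d, d, pairing = "random", seed = 8)
  expect_equal(r1$pairs, r2$pairs)
  expect_equal(r1$n_pairs, rep_same$n_pairs)   # same number of pairs as corresponding

  other <- random_pwm_dataset(n = 3)
  names(other$pwms) <- c("QQQQ", "WWWW", "YYYY")
  expect_error(across_dataset_agreement(d, other), "share no core")
})

test_that("uniform columns are excluded from agreement fractions unless exactly equal", {
  u <- cbind(rep(0.25, 4)); v <- cbind(c(0.7, 0.1, 0.1, 0.1))
  d1 <- pwm_dataset(list(AK = u, AR = v))
  d2 <- pwm_dataset(list(AK = u, AR = v))
  rep1 <- across_dataset_agreement(d1, d2)
  expect_equal(rep1$n_undefined_pcc, 0L)      # equal uniform columns agree
  expect_equal(rep1$fraction_agreeing, 1)
  d3 <- pwm_dataset(list(AK = cbind(c(0.4, 0.2, 0.2, 0.2)), AR = v))
  rep2 <- across_dataset_agreement(d1, d3)
  expect_equal(rep2$n_undefined_pcc, 1L)      # uniform vs non-uniform: excluded
  expect_equal(rep2$fraction_agreeing, 1)     # over the one defined pair
})

test_that("gain/loss fractions come from the initial-agreement partition", {
  nms <- c("AAAA", "RRRR", "CCCC", "DDDD")
  agree0 <- cbind(c(0.9, 0.05, 0.03, 0.02))
  # initial: two agreeing pairs, two disagreeing pairs (k = 1)
  i1 <- pwm_dataset(setNames(list(agree0, agree0, cbind(onehot(1)), cbind(onehot(2))), nms))
  i2 <- pwm_dataset(setNames(list(agree0, agree0, cbind(onehot(2)), cbind(onehot(3))), nms))
  # revised: both disagreeing pairs swap in, no agreeing pair swaps out
  r1 <- pwm_dataset(setNames(list(agree0, agree0, agree0, agree0), nms))
  r2 <- pwm_dataset(setNames(list(agree0, agree0, agree0, agree0), nms))
  gl <- gain_loss(i1, i2, r1, r2)
  expect_equal(gl$gain, 1)
  expect_equal(gl$loss, 0)
  expect_true(is.na(gl$enrichment))
  expect_equal(gl$n_initially_disagreeing, 2L)
  expect_equal(gl$n_initially_agreeing, 2L)

  # with roles swapped, all four pairs start agreeing: half fall out, and
  # the gain fraction is undefined (empty disagreeing partition)
  rev_gl <- gain_loss(r1, r2, i1, i2)
  expect_equal(rev_gl$n_initially_agreeing, 4L)
  expect_equal(rev_gl$loss, 0.5)
  expect_true(is.na(rev_gl$gain))

  same <- gain_loss(i1, i2, i1, i2)
  expect_equal(same$gain, 0)
  expect_equal(same$loss, 0)
  expect_true(is.na(same$enrichment))
})

test_that("Jaccard overlap follows the set formula with the empty-set convention", {
  expect_equal(jaccard_agreement_overlap(c("a:1", "b:2"), c("a:1", "b:2")), 1)
  expect_equal(jaccard_agreement_overlap(c("a:1"), c("b:2")), 0)
  expect_equal(jaccard_agreement_overlap(c("a:1", "b:1", "c:1"),
                                         c("a:1", "b:1", "c:1", "d:1")), 0.75)
  expect_message(j <- jaccard_agreement_overlap(character(0), character(0)), "empty")
  expect_equal(j, 1)
})

test_that("external comparison reports the agreement delta with a random control", {
  nms <- c("AAAA", "RRRR")
  ext <- pwm_dataset(setNames(list(cbind(onehot(1)), cbind(onehot(2))), nms))
  init <- pwm_dataset(setNames(list(cbind(onehot(3)), cbind(onehot(4))), nms))
  same <- external_comparison(init, ext, init, seed = 2)
  expect_equal(same$delta, 0)

  cmp <- external_comparison(ext, ext, init, seed = 2)
  expect_equal(cmp$fraction_revised, 1)
  expect_equal(cmp$fraction_initial, 0)
  expect_equal(cmp$delta, 1)
  cmp2 <- external_comparison(ext, ext, init, seed = 2)
  expect_equal(cmp$fraction_revised_random, cmp2$fraction_revised_random)
  expect_equal(cmp$n_shared_cores, 2L)
})
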