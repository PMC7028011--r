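test_that("alpha = 1 is the exact identity and isolated nodes never move", {
  set.seed(14)
  S <- random_prob_rows(6)
  g <- random_graph(rownames(S)[1:4])
  expect_identical(qp_infer_column(S, g, alpha = 1), S)
  expect_equal(unclass(lpa_infer_column(S, g, alpha = 1))[, ], S,
               ignore_attr = TRUE)
  # rows outside the graph, and graph nodes without edges, stay put
  g_iso <- similarity_graph(1L, rownames(S),
                            data.frame(from = rownames(S)[1:2],
                                       to = rownames(S)[2:1], weight = c(1, 1)))
  for (alpha in c(0.2, 0.7)) {
    q <- qp_infer_column(S, g_iso, alpha)
    l <- lpa_infer_column(S, g_iso, alpha)
    expect_equal(q[3:6, ], S[3:6, ])
    expect_equal(l[3:6, ], S[3:6, ])
  }
})

test_that("single-iteration propagation is the weighted nearest-neighbor blend", {
  set.seed(15)
  for (rep in 1:10) {
    S <- random_prob_rows(8)
    g <- random_graph(rownames(S))
    W <- weight_matrix(g, rownames(S))
    alpha <- runif(1, 0.1, 0.9)
    blend <- alpha * S + (1 - alpha) * W %*% S
    for (variant in c("anchored", "literal")) {
      one <- suppressWarnings(lpa_infer_column(S, g, alpha, max_iter = 1L,
                                               variant = variant))
      expect_equal(unclass(one)[, ], blend[, ], tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("anchored propagation reaches the linear-system fixed point; literal drifts to consensus", {
  set.seed(16)
  S <- random_prob_rows(5)
  g <- random_graph(rownames(S))
  W <- weight_matrix(g, rownames(S))
  fp <- oracle_lpa_fixed_point(S, W, alpha = 0.4)
  anc <- lpa_infer_column(S, g, alpha = 0.4, tol = 1e-12)
  expect_equal(unclass(anc)[, ], fp[, ], tolerance = 1e-9, ignore_attr = TRUE)

  lit <- suppressWarnings(lpa_infer_column(S, g, alpha = 0.4, max_iter = 2000L,
                                           variant = "literal", tol = 1e-10))
  # literal update on a connected graph loses the anchor: rows approach a
  # common consensus, unlike the anchored fixed point
  spread_lit <- max(apply(lit, 2, function(x) diff(range(x))))
  spread_anc <- max(apply(anc, 2, function(x) diff(range(x))))
  expect_lt(spread_lit, 0.05)
  expect_gt(spread_anc, spread_lit)
})

test_that("both solvers conserve the probability simplex", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    S <- random_prob_rows(n)
    g <- random_graph(rownames(S))
    alpha <- runif(1, 0.05, 1)
    for (X in list(qp_infer_column(S, g, alpha),
                   lpa_infer_column(S, g, alpha))) {
      expect_true(all(X >= -1e-12 & X <= 1 + 1e-12))
      expect_true(all(abs(rowSums(X) - 1) < 1e-9))
    }
  }
})

test_that("the QP solution improves the objective and obeys monotone smoothing", {
  set.seed(18)
  S <- random_prob_rows(6)
  g <- random_graph(rownames(S))
  W <- weight_matrix(g, rownames(S))
  alphas <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  penalties <- numeric(length(alphas))
  for (i in seq_along(alphas)) {
    X <- qp_infer_column(S, g, alphas[i])
    expect_lte(smoothing_objective(X, S, W, alphas[i]),
               smoothing_objective(S, S, W, alphas[i]) + 1e-12)
    idx <- which(W > 0, arr.ind = TRUE)
    penalties[i] <- sum(W[idx] * rowSums((X[idx[, 1], , drop = FALSE] -
                                          X[idx[, 2], , drop = FALSE])^2))
  }
  # more smoothing (smaller alpha) never increases the coupling penalty
  expect_true(all(diff(penalties) <= 1e-10))
})

test_that("joint_infer revises only the requested positions and degrades gracefully", {
  set.seed(19)
  d <- pwm_dataset(list(AK = random_pwm(), AR = random_pwm(), DD = random_pwm()))
  graphs <- lapply(1:3, function(j) {
    similarity_graph(j, cores(d), data.frame(from = c("AK", "AR"),
                                             to = c("AR", "AK"), weight = c(1, 1)))
  })
  fit <- joint_infer(d, graphs, alpha = 0.5, positions = 1L)
  expect_s3_class(fit, "joint_infer")
  for (cs in cores(d)) {
    expect_equal(coef(fit)[[cs]][, 2:3], d$pwms[[cs]][, 2:3])
  }
  expect_false(isTRUE(all.equal(coef(fit)$AK[, 1], d$pwms$AK[, 1])))
  expect_equal(coef(fit)$DD, d$pwms$DD)    # isolated core untouched

  none <- joint_infer(d, graphs, alpha = 0.5, positions = integer(0))
  expect_equal(coef(none), d$pwms)

  empty <- lapply(1:3, function(j)
    similarity_graph(j, cores(d), data.frame(from = character(0),
                                             to = character(0), weight = numeric(0))))
  expect_equal(coef(joint_infer(d, empty, alpha = 0.3)), d$pwms)

  expect_error(joint_infer(d, graphs, alpha = 0), "alpha")
  expect_error(joint_infer(d, graphs, alpha = 0.5, positions = 7L), "position")

  # residuals/fitted/summary accessors are consistent
  r <- residuals(fit)
  expect_equal(d$pwms$AK + r$AK, coef(fit)$AK)
  s <- summary(fit)
  expect_equal(unname(s$max_change["DD"]), 0)
})

test_that("solver errors carry the binding-site position", {
  d <- pwm_dataset(list(AK = random_pwm(k = 1), AR = random_pwm(k = 1)))
  g_bad <- similarity_graph(1L, c("AK", "ZZ"),
                            data.frame(from = c("AK", "ZZ"), to = c("ZZ", "AK"),
                                       weight = c(1, 1)))
  expect_error(joint_infer(d, list(g_bad), alpha = 0.5), "position 1")
})
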