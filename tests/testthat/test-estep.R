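test_that("artificial weights match the direct summation example", {
  # N=2, one item, both posteriors (1/2, 1/2) on a 2-point grid, y = (1, 0):
  # f = (1, 1), r = (1/2, 1/2), both weight slices (1/2, 1/2)
  Y <- matrix(c(1, 0), 2, 1)
  post <- posterior_table(Y, matrix(0, 1, 1), 0, diag(1),
                          build_grid(2, c(-1, 1), 1))
  art <- artificial_weights(Y, post)
  expect_equal(art$f, c(1, 1))
  expect_equal(art$r[1, ], c(0.5, 0.5))
  expect_equal(art$w[1, "1", ], c(0.5, 0.5))
  expect_equal(art$w[1, "0", ], c(0.5, 0.5))
})

test_that("artificial weights: degenerate responses and mass conservation", {
  inst <- tiny_instance(3, N = 15, J = 3)
  Y1 <- inst$Y; Y1[, 2] <- 1          # every subject answers item 2 positively
  post <- suppressWarnings(
    posterior_table(Y1, inst$A, inst$b, inst$Sigma, inst$grid))
  art <- artificial_weights(Y1, post)
  expect_equal(art$w[2, "0", ], rep(0, inst$grid$G))
  expect_equal(art$r[2, ], art$f, tolerance = 1e-12)
  # sum over z and g recovers N for every item; r within [0, f]
  for (j in 1:3) {
    expect_equal(sum(art$w[j, , ]), nrow(Y1), tolerance = 1e-9)
    expect_true(all(art$r[j, ] >= 0 & art$r[j, ] <= art$f + 1e-12))
  }
  expect_equal(sum(art$f), nrow(Y1), tolerance = 1e-9)
  expect_error(artificial_weights(inst$Y[, 1:2], post), "match")
})

test_that("scatter matrix: point mass, symmetry, brute-force oracle", {
  # all mass on theta = (1, -1)
  g <- build_grid(2, c(-1, 1), 2)    # points: (-1,-1), (-1,1), (1,-1), (1,1)
  post <- structure(list(weights = matrix(c(0, 0, 1, 0), 1, 4),
                         counts = 1L, N = 1L), class = "m2pl_posterior")
  expect_equal(scatter_matrix(post, g),
               matrix(c(1, -1, -1, 1), 2), tolerance = 1e-14)
  # posterior = prior with Sigma = I on a symmetric grid: off-diagonals vanish
  gs <- build_grid(5, c(-3, 3), 2)
  ps <- posterior_table(matrix(0, 4, 2), matrix(0, 2, 2), c(0, 0), diag(2), gs)
  Ss <- scatter_matrix(ps, gs)
  expect_lt(abs(Ss[1, 2]), 1e-12)
  # brute-force double loop
  inst <- tiny_instance(7, N = 10)
  post <- posterior_table(inst$Y, inst$A, inst$b, inst$Sigma, inst$grid)
  expect_equal(scatter_matrix(post, inst$grid),
               bf_scatter(post$weights, inst$grid), tolerance = 1e-12)
})

test_that("discretized standard-normal prior has near-identity scatter", {
  g <- grid11(2)
  post <- posterior_table(matrix(0, 2, 2), matrix(0, 2, 2), c(0, 0), diag(2), g)
  S <- scatter_matrix(post, g)
  # +-4 truncation at 11 points is inexact; diagonal within 10% of 1
  expect_true(all(abs(diag(S) - 1) < 0.1))
  expect_lt(max(abs(S[upper.tri(S)])), 1e-12)
})

test_that("Q0 matches its closed form and rejects bad covariances", {
  expect_equal(q0_value(diag(1), matrix(1, 1, 1), 10),
               -5 * (log(2 * pi) + 1), tolerance = 1e-12)
  expect_equal(q0_value(diag(1), matrix(1, 1, 1), 10), -14.18938533,
               tolerance = 1e-8)
  # Sigma = I reduces to -N/2 (K log 2pi + tr S*)
  S <- matrix(c(0.9, 0.2, 0.2, 1.1), 2)
  expect_equal(q0_value(diag(2), S, 7),
               -3.5 * (2 * log(2 * pi) + sum(diag(S))), tolerance = 1e-12)
  expect_error(q0_value(matrix(c(1, 2, 2, 1), 2), S, 7), "positive definite")
})

test_that("naive and regrouped per-item surrogates are identical", {
  for (seed in 1:6) {
    inst <- tiny_instance(seed, N = 20, J = 3, K = 2, per_dim = 3)
    post <- posterior_table(inst$Y, inst$A, inst$b, inst$Sigma, inst$grid)
    art <- artificial_weights(inst$Y, post)
    for (j in 1:3) {
      qn <- qj_value(inst$A[j, ], inst$b[j], j, inst$grid, mode = "naive",
                     Y = inst$Y, post = post, eta = 0.7)
      qw <- qj_value(inst$A[j, ], inst$b[j], j, inst$grid, mode = "weighted",
                     art = art, eta = 0.7)
      expect_equal(qn, qw, tolerance = 1e-12)
      # and both agree with a straight-line double-loop evaluation
      expect_equal(qw, bf_qj(inst$A[j, ], inst$b[j], inst$Y[, j],
                             post$weights, inst$grid, 0.7),
                   tolerance = 1e-10)
    }
  }
})

test_that("per-item surrogate: flat-parameter value and penalty linearity", {
  inst <- tiny_instance(8, N = 25, J = 2, K = 2)
  post <- posterior_table(inst$Y, inst$A, inst$b, inst$Sigma, inst$grid)
  art <- artificial_weights(inst$Y, post)
  # all Bernoulli terms are log(1/2) and the weights sum to N
  expect_equal(qj_value(c(0, 0), 0, 1, inst$grid, art = art, eta = 0),
               -25 * log(2), tolerance = 1e-10)
  # with ||a_j||_1 = 1, raising eta by delta lowers the value by delta
  a <- c(0.4, -0.6)
  q1 <- qj_value(a, 0.2, 1, inst$grid, art = art, eta = 1)
  q3 <- qj_value(a, 0.2, 1, inst$grid, art = art, eta = 3)
  expect_equal(q1 - q3, 2, tolerance = 1e-12)
})

test_that("surrogate components add up", {
  inst <- tiny_instance(9, N = 12, J = 3)
  post <- posterior_table(inst$Y, inst$A, inst$b, inst$Sigma, inst$grid)
  art <- artificial_weights(inst$Y, post)
  S <- scatter_matrix(post, inst$grid)
  qc <- q_components(inst$A, inst$b, inst$Sigma, art, S, inst$grid, 0.5)
  expect_equal(qc$total, qc$q0 + sum(qc$qj), tolerance = 1e-10)
})
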