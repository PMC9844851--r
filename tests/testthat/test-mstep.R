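test_that("soft-thresholding operator", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(c(-2, 0.3, 4), 0), c(-2, 0.3, 4))
  expect_error(soft_threshold(1, -1), "non-negative")
})

test_that("full shrinkage leaves the closed-form weighted intercept", {
  # eta beyond N * max|theta|: all loadings 0, b = log(W1/W0)
  g <- build_grid(5, c(-4, 4), 1)
  X <- rbind(g$points, g$points)
  z <- c(rep(1, 5), rep(0, 5))
  w <- c(rep(6, 5), rep(14, 5))          # W1 = 30, W0 = 70
  fit <- fit_item_weighted_l1(X, z, w, eta = 1e6)
  expect_identical(fit$a, 0)
  expect_equal(fit$b, log(30 / 70), tolerance = 1e-10)
  expect_equal(fit$b, -0.84729786, tolerance = 1e-8)
  # all-true mask gives the same intercept regardless of eta
  fit2 <- fit_item_weighted_l1(X, z, w, eta = 0, fixed_zero = TRUE)
  expect_identical(fit2$a, 0)
  expect_equal(fit2$b, log(30 / 70), tolerance = 1e-10)
})

test_that("unpenalized toy solution matches a dense grid-search oracle", {
  g <- build_grid(2, c(-1, 1), 1)
  X <- rbind(g$points, g$points)
  z <- c(1, 1, 0, 0)
  w <- c(3, 1, 0.5, 2.5)
  fit <- fit_item_weighted_l1(X, z, w, eta = 0)
  obj <- function(a, b) {
    lp <- X[, 1] * a + b
    sum(w * (z * lp - log1p(exp(lp))))
  }
  # coarse-to-fine grid search, independent of the solver
  best <- c(0, 0)
  for (scale in c(1, 0.1, 0.01, 1e-3, 1e-4)) {
    cand <- expand.grid(a = best[1] + seq(-5, 5) * scale,
                        b = best[2] + seq(-5, 5) * scale)
    vals <- mapply(obj, cand$a, cand$b)
    best <- unlist(cand[which.max(vals), ])
  }
  expect_equal(fit$a, unname(best[1]), tolerance = 1e-4)
  expect_equal(fit$b, unname(best[2]), tolerance = 1e-4)
})

test_that("solver agrees with glmnet on weighted penalized problems", {
  skip_if_not_installed("glmnet")
  set.seed(3)
  for (rep in 1:4) {
    G <- 20; K <- 3
    X <- matrix(runif(2 * G * K, -3, 3), 2 * G, K)
    z <- rep(c(1, 0), each = G)
    w <- runif(2 * G, 0.1, 5)
    eta <- runif(1, 0.5, 6)
    mine <- fit_item_weighted_l1(X, z, w, eta)
    gl <- glmnet::glmnet(X, z, family = "binomial", weights = w,
                         lambda = eta / sum(w), standardize = FALSE,
                         thresh = 1e-14)
    expect_equal(mine$a, as.numeric(gl$beta), tolerance = 1e-6)
    expect_equal(mine$b, as.numeric(gl$a0), tolerance = 1e-6)
  }
})

test_that("solutions satisfy the subgradient KKT conditions", {
  set.seed(17)
  for (rep in 1:10) {
    K <- sample(1:4, 1)
    G <- 16
    X <- matrix(runif(2 * G * K, -3, 3), 2 * G, K)
    z <- rep(c(1, 0), each = G)
    w <- runif(2 * G, 0, 4)
    eta <- runif(1, 0, 8)
    mask <- runif(K) < 0.2
    fit <- fit_item_weighted_l1(X, z, w, eta, fixed_zero = mask)
    expect_true(all(fit$a[mask] == 0))
    expect_true(kkt_ok(fit, eta, fixed_zero = mask, tol = 1e-6))
    # inactive penalized coordinates are exact zeros (never tiny values):
    # every free coordinate is either exactly 0 or strictly beyond 1e-8
    free_a <- fit$a[!mask]
    expect_true(all(free_a == 0 | abs(free_a) > 1e-8))
  }
})

test_that("separated intercept is capped at +-30 with a warning", {
  g <- build_grid(3, c(-1, 1), 1)
  X <- rbind(g$points, g$points)
  z <- c(rep(1, 3), rep(0, 3))
  w <- c(rep(2, 3), rep(0, 3))           # no mass in the z = 0 class
  expect_warning(fit <- fit_item_weighted_l1(X, z, w, eta = 0,
                                             fixed_zero = TRUE),
                 "separation")
  expect_equal(fit$b, 30)
  expect_true(fit$separated)
})

test_that("covariance update reaches the stationary point", {
  # S* = I is a fixed point
  out <- update_covariance(diag(2), diag(2), 50)
  expect_equal(unclass(out), diag(2), ignore_attr = TRUE, tolerance = 1e-12)
  # K = 2 with unit-diagonal S*: the stationary correlation equals s
  for (s in c(-0.5, 0.1, 0.3, 0.7)) {
    S <- matrix(c(1, s, s, 1), 2)
    out <- update_covariance(S, diag(2), 100)
    expect_equal(out[1, 2], s, tolerance = 1e-6)
    expect_equal(diag(out), c(1, 1))
    ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
  # independent 1-D grid-search oracle over the correlation
  S <- matrix(c(1, 0.3, 0.3, 1), 2)
  q0_rho <- function(rho) {
    Sg <- matrix(c(1, rho, rho, 1), 2)
    q0_value(Sg, S, 100)
  }
  rhos <- seq(-0.99, 0.99, by = 1e-4)
  rho_star <- rhos[which.max(sapply(rhos, q0_rho))]
  out <- update_covariance(S, diag(2), 100)
  expect_equal(out[1, 2], rho_star, tolerance = 1e-4)
})

test_that("covariance update never decreases Q0 and handles K = 3", {
  set.seed(23)
  for (rep in 1:5) {
    M <- matrix(rnorm(9), 3); S <- crossprod(M) / 3 + diag(3) * 0.5
    init <- diag(3)
    out <- update_covariance(S, init, 40)
    expect_gte(q0_value(out, S, 40), q0_value(init, S, 40) - 1e-9)
    expect_equal(diag(out), rep(1, 3))
    expect_gt(min(eigen(out, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})
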