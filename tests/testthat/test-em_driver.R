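# A small shared fit keeps these tests fast: N = 150, J = 6, K = 2, 7-point
# grid, a design with one cross-loading item.
make_small_world <- function(seed = 31, N = 150) {
  Lambda <- cbind(c(1, 0, 1, 1, 0, 1), c(0, 1, 0, 1, 1, 1))
  cfg <- sim_config(N, J = 6, K = 2, structure = Lambda, seed = seed)
  model <- generate_true_model(cfg)
  Y <- generate_responses(model, N, seed = seed + 1)
  list(model = model, Y = Y, config = model$config,
       grid = build_grid(7, c(-4, 4), 2))
}

test_that("default initialization follows the standard protocol", {
  cfg <- m2pl_config(500, 40, 3)
  init <- default_init(cfg)
  expect_equal(init$A[1, ], c(1, 0, 0))
  expect_equal(init$A[10, ], c(0, 1, 0))
  expect_equal(init$A[19, ], c(0, 0, 1))
  expect_equal(init$A[2, ], rep(1 / 40, 3))   # = 0.025
  expect_equal(init$b, rep(0, 40))
  expect_identical(init$Sigma, diag(3))
})

test_that("EM fit: surrogate ascent, anchor zeros, convergence", {
  w <- make_small_world()
  fit <- em_fit(w$Y, eta = 0.03 * w$config$N, w$config, w$grid)
  expect_true(fit$converged)
  expect_gte(fit$ascent_slack, -1e-9)
  mask <- fixed_zero_mask(w$config)
  expect_true(all(fit$A[mask] == 0))
  expect_equal(diag(fit$Sigma), c(1, 1))
  expect_equal(fit$Lambda, loading_structure(fit$A))
})

test_that("IEML1 and naive EML1 agree to machine precision on shared inputs", {
  w <- make_small_world(N = 120)
  f1 <- em_fit(w$Y, eta = 4, w$config, w$grid, variant = "ieml1",
               sigma_fixed = w$model$Sigma)
  f2 <- em_fit(w$Y, eta = 4, w$config, w$grid, variant = "eml1",
               sigma_fixed = w$model$Sigma)
  expect_equal(f1$n_iter, f2$n_iter)
  expect_lt(max(abs(f1$A - f2$A)), 1e-13)
  expect_lt(max(abs(f1$b - f2$b)), 1e-13)
})

test_that("BIC arithmetic: spurious loadings cost log N, ties are exact", {
  cfg <- m2pl_config(150, 6, 2, c(`1` = 1, `2` = 2))
  Lambda <- rbind(diag(2), matrix(c(1L, 0L), 4, 2, byrow = TRUE))
  fit <- structure(list(loglik = -100, config = cfg, Lambda = Lambda,
                        sigma_known = FALSE), class = "m2pl_fit")
  # d = 6 nonzero loadings + 6 difficulties + 1 covariance entry
  expect_equal(bic_m2pl(fit, NULL, NULL), 200 + 13 * log(150))
  # identical structure and likelihood give identical BIC
  expect_equal(bic_m2pl(fit, NULL, NULL), bic_m2pl(fit, NULL, NULL))
  # one extra nonzero free loading with no likelihood change costs log N
  fit2 <- fit; fit2$Lambda[3, 2] <- 1L
  expect_equal(bic_m2pl(fit2, NULL, NULL) - bic_m2pl(fit, NULL, NULL),
               log(150), tolerance = 1e-12)
  # anchor-row extra entries never enter d (they are fixed zeros)
  fit3 <- fit; fit3$Lambda[1, 2] <- 1L
  expect_equal(bic_m2pl(fit3, NULL, NULL), bic_m2pl(fit, NULL, NULL))
  # degrees of freedom drop the covariance count when Sigma was fixed
  fitk <- fit; fitk$sigma_known <- TRUE
  expect_equal(bic_m2pl(fit, NULL, NULL) - bic_m2pl(fitk, NULL, NULL),
               log(150))
})

test_that("tuning path selects the minimum-BIC fit; singleton paths work", {
  w <- make_small_world()
  etas <- c(0.05, 0.02) * w$config$N
  path <- fit_path(w$Y, etas, w$config, w$grid)
  expect_equal(path$etas, sort(etas, decreasing = TRUE))
  expect_equal(path$bic[path$selected], min(path$bic, na.rm = TRUE))
  single <- fit_path(w$Y, 0.03 * w$config$N, w$config, w$grid)
  expect_equal(single$selected, 1L)
  # refit BIC never selects a candidate whose refit failed to beat it
  expect_true(all(!is.na(path$bic)))
})

test_that("confirmatory structure constraints hold bitwise in refits", {
  w <- make_small_world()
  fit <- em_fit(w$Y, eta = 0.05 * w$config$N, w$config, w$grid)
  zeros <- fit$Lambda == 0
  rf <- em_fit(w$Y, 0, w$config, w$grid, structure_zeros = zeros,
               init = list(A = fit$A, b = fit$b, Sigma = fit$Sigma))
  expect_true(all(rf$A[zeros] == 0))
  expect_gte(rf$loglik, fit$loglik)   # unpenalized refit can only gain
})

test_that("two-stage: stage 2 never modifies the stage-1 covariance", {
  w <- make_small_world()
  ts <- two_stage_fit(w$Y, c(0.05, 0.02) * w$config$N, w$config, w$grid)
  expect_identical(ts$Sigma, ts$stage1$Sigma)
  expect_true(ts$sigma_known)
  expect_false(ts$stage1$sigma_known)
})

test_that("unpenalized estimates approach the truth as N grows", {
  # consistency of the known-Sigma MLE: aggregate loading MSE shrinks with
  # the sample size (3 replications per N; scaled-down check)
  Lambda <- cbind(c(1, 0, 1, 1, 0, 1, 1, 0), c(0, 1, 0, 1, 1, 0, 1, 1))
  mse_at <- function(N) {
    cfg <- sim_config(N, J = 8, K = 2, structure = Lambda, seed = 71)
    model <- generate_true_model(cfg)
    grid <- build_grid(5, c(-4, 4), 2)
    mean(sapply(1:3, function(r) {
      Y <- generate_responses(model, N, seed = replication_seed(71, r))
      # a loose iteration cap suffices for an MSE comparison
      fit <- em_fit(Y, 0, model$config, grid, sigma_fixed = model$Sigma,
                    control = em_control(max_iter = 150))
      mean((fit$A - model$A)^2)
    }))
  }
  expect_lt(mse_at(800), mse_at(150))
})

test_that("eta grids expand to the documented candidate sets", {
  expect_equal(eta_grid(1000, "coarse"), seq(0.10, 0.01, by = -0.01) * 1000)
  expect_length(eta_grid(500, "coarse"), 10L)
  expect_equal(eta_grid(754, "fine"), seq(0.040, 0.002, by = -0.002) * 754)
  expect_length(eta_grid(754, "fine"), 20L)
})
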