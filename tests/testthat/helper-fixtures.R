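# Small random instances and straight-line brute-force oracles used across
# the test files.  The oracles deliberately share no code with the package
# internals: plain double loops over subjects and grid points.

tiny_instance <- function(seed, N = 20, J = 3, K = 2, per_dim = 3) {
  set.seed(seed)
  A <- matrix(runif(J * K, -1.5, 1.5), J, K)
  b <- rnorm(J)
  Sigma <- diag(K)
  if (K > 1) Sigma[1, 2] <- Sigma[2, 1] <- 0.3
  grid <- build_grid(per_dim, c(-2, 2), K)
  Y <- matrix(rbinom(N * J, 1, 0.5), N, J)
  list(A = A, b = b, Sigma = Sigma, Y = Y, grid = grid,
       N = N, J = J, K = K)
}

bf_dmvnorm <- function(x, Sigma) {
  K <- length(x)
  exp(-0.5 * drop(t(x) %*% solve(Sigma) %*% x)) /
    sqrt((2 * pi)^K * det(Sigma))
}

# observed log-likelihood by explicit double loop (normalized prior mass)
bf_loglik <- function(A, b, Sigma, Y, grid) {
  G <- grid$G
  phi <- sapply(seq_len(G), function(g) bf_dmvnorm(grid$points[g, ], Sigma))
  pi_g <- phi / sum(phi)
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    tot <- 0
    for (g in seq_len(G)) {
      pr <- 1
      for (j in seq_len(ncol(Y))) {
        F <- 1 / (1 + exp(-(sum(A[j, ] * grid$points[g, ]) + b[j])))
        pr <- pr * ifelse(Y[i, j] == 1, F, 1 - F)
      }
      tot <- tot + pi_g[g] * pr
    }
    ll <- ll + log(tot)
  }
  ll
}

# posterior table by explicit loops
bf_posterior <- function(A, b, Sigma, Y, grid) {
  G <- grid$G
  W <- matrix(0, nrow(Y), G)
  for (i in seq_len(nrow(Y))) {
    for (g in seq_len(G)) {
      pr <- bf_dmvnorm(grid$points[g, ], Sigma)
      for (j in seq_len(ncol(Y))) {
        F <- 1 / (1 + exp(-(sum(A[j, ] * grid$points[g, ]) + b[j])))
        pr <- pr * ifelse(Y[i, j] == 1, F, 1 - F)
      }
      W[i, g] <- pr
    }
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

bf_scatter <- function(W, grid) {
  K <- ncol(grid$points)
  S <- matrix(0, K, K)
  for (i in seq_len(nrow(W)))
    for (g in seq_len(ncol(W)))
      S <- S + W[i, g] * tcrossprod(grid$points[g, ])
  S / nrow(W)
}

# naive per-item surrogate by explicit loops (Bernoulli log-lik form)
bf_qj <- function(a_j, b_j, y_col, W, grid, eta) {
  val <- 0
  for (i in seq_len(nrow(W))) {
    for (g in seq_len(ncol(W))) {
      lp <- sum(a_j * grid$points[g, ]) + b_j
      F <- 1 / (1 + exp(-lp))
      val <- val + W[i, g] * (y_col[i] * log(F) + (1 - y_col[i]) * log(1 - F))
    }
  }
  val - eta * sum(abs(a_j))
}
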