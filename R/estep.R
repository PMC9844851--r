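## E-step quantities: artificial data (expected counts), the scatter matrix
## of the posterior, and the two algebraically identical forms of the
## per-item surrogate Q~_j.
##
## The artificial data are the classical Bock-Aitkin expected counts: at each
## ability level theta_g, f_g is the expected number of subjects located
## there and r_jg the expected number of positive responses to item j.  The
## pair (f_g - r_jg, r_jg) acts as weights w_j(z, theta_g) on 2 x G
## pseudo-observations (z, theta_g), z in {0, 1} -- the regrouping that turns
## the naive N x G M-step into a 2 x G one without changing the objective.

#' Artificial data (expected counts) from a posterior table
#'
#' @param Y The response matrix the posterior table was built from.
#' @param post A [posterior_table()] object.
#' @return An object of class `m2pl_artificial` with `f` (length G,
#'   `sum(f) == N`), `r` (J x G), and `w` (J x 2 x G array;
#'   `w[j, "1", ] == r[j, ]`, `w[j, "0", ] == f - r[j, ]`).  Weights below
#'   1e-300 are clamped to zero.
#' @export
artificial_weights <- function(Y, post) {
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  if (!inherits(post, "m2pl_posterior")) stop("post must be a posterior table")
  if (nrow(Y) != post$N || ncol(Y) != ncol(post$patterns))
    stop("Y does not match the posterior table")
  Wc <- post$weights * post$counts            # counts recycle down rows
  f <- colSums(Wc)
  r <- t(post$patterns) %*% Wc                # J x G
  r[r < 1e-300] <- 0
  r <- pmin(r, rep(f, each = nrow(r)))        # guard rounding: r <= f exactly
  w0 <- f - t(r)                              # G x J under the hood
  w0[w0 < 1e-300] <- 0
  G <- length(f); J <- nrow(r)
  w <- array(0, dim = c(J, 2L, G), dimnames = list(NULL, c("0", "1"), NULL))
  w[, "1", ] <- r
  w[, "0", ] <- t(w0)
  structure(list(f = f, r = r, w = w, N = post$N, J = J, G = G),
            class = "m2pl_artificial")
}

#' Posterior scatter matrix of the latent traits
#'
#' `S* = N^{-1} sum_i sum_g theta_g theta_g' p(theta_g | y_i)` -- the expected
#' second moment of the latent traits under the discrete posterior, the
#' sufficient statistic for the covariance update.
#'
#' @param post A [posterior_table()] object.
#' @param grid The grid the table was built on.
#' @return K x K symmetric positive-semidefinite matrix.
#' @export
scatter_matrix <- function(post, grid) {
  m <- colSums(post$weights * post$counts)    # expected mass per grid point
  S <- crossprod(grid$points, grid$points * m) / post$N
  (S + t(S)) / 2
}

#' Covariance part of the EM surrogate
#'
#' `Q~0(Sigma) = -1/2 { N K log(2 pi) + N log det Sigma + N tr(Sigma^{-1} S*) }`,
#' using a Cholesky-based log-determinant.
#'
#' @param Sigma Unit-diagonal positive-definite covariance.
#' @param S_star Scatter matrix from [scatter_matrix()].
#' @param N Number of subjects.
#' @return Scalar.
#' @export
q0_value <- function(Sigma, S_star, N) {
  R <- tryCatch(chol(Sigma), error = function(e) stop("Sigma must be positive definite"))
  K <- ncol(Sigma)
  logdet <- 2 * sum(log(diag(R)))
  tr <- sum(chol2inv(R) * S_star)
  -0.5 * (N * K * log(2 * pi) + N * logdet + N * tr)
}

#' Per-item surrogate Q~_j, naive or regrouped form
#'
#' Evaluates the expected penalized Bernoulli log-likelihood for one item,
#' either by the naive double sum over subjects and grid points (weights
#' `p(theta_g | y_i)`) or by the regrouped single sum over the 2 x G
#' artificial observations.  The two forms are algebraically identical; their
#' agreement on shared inputs is the correctness check for the acceleration.
#'
#' @param a_j Length-K discrimination vector for the item.
#' @param b_j Difficulty.
#' @param item Item index j.
#' @param grid The quadrature grid.
#' @param mode `"weighted"` (artificial data) or `"naive"`.
#' @param art For `mode = "weighted"`: an [artificial_weights()] object.
#' @param Y,post For `mode = "naive"`: the response matrix and its
#'   [posterior_table()].
#' @param eta Penalty weight; the term `- eta * sum(abs(a_j))` is included.
#' @return Scalar Q~_j value.
#' @export
qj_value <- function(a_j, b_j, item, grid, mode = c("weighted", "naive"),
                     art = NULL, Y = NULL, post = NULL, eta = 0) {
  mode <- match.arg(mode)
  lp <- drop(grid$points %*% a_j) + b_j
  logF <- stats::plogis(lp, log.p = TRUE)
  log1mF <- stats::plogis(-lp, log.p = TRUE)
  if (mode == "weighted") {
    if (is.null(art)) stop("weighted mode needs 'art'")
    val <- sum(art$r[item, ] * logF) + sum((art$f - art$r[item, ]) * log1mF)
  } else {
    if (is.null(Y) || is.null(post)) stop("naive mode needs 'Y' and 'post'")
    if (!is.matrix(Y)) Y <- as.matrix(Y)
    y <- post$patterns[, item]
    Wc <- post$weights * post$counts
    val <- sum(Wc * (outer(y, logF) + outer(1 - y, log1mF)))
  }
  val - eta * sum(abs(a_j))
}

#' Total EM surrogate at given parameters
#'
#' `Q~ = Q~0 + sum_j Q~j`, evaluated through the artificial data.
#'
#' @param A,b,Sigma Parameters at which to evaluate the surrogate.
#' @param art Artificial data from the E-step defining the surrogate.
#' @param S_star Scatter matrix from the same E-step.
#' @param grid Quadrature grid.
#' @param eta Penalty weight.
#' @return List with `q0`, `qj` (length J) and `total`.
#' @export
q_components <- function(A, b, Sigma, art, S_star, grid, eta) {
  q0 <- q0_value(Sigma, S_star, art$N)
  qj <- vapply(seq_len(art$J), function(j) {
    qj_value(A[j, ], b[j], j, grid, mode = "weighted", art = art, eta = eta)
  }, numeric(1))
  list(q0 = q0, qj = qj, total = q0 + sum(qj))
}
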