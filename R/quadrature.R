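## Fixed quadrature grids, the discrete posterior over the latent traits and
## response-pattern grouping.
##
## The E-step approximates the posterior p(theta_i | y_i) by restricting theta
## to a K-ary Cartesian power of equally spaced points.  Identical response
## rows share identical posteriors, so the table can be built over distinct
## patterns with multiplicities.

#' Build a Cartesian-power quadrature grid
#'
#' Equally spaced points per dimension (both endpoints included), expanded to
#' the K-ary Cartesian power in lexicographic order with the last dimension
#' varying fastest.  The standard choices are `Grid11` (11 points on
#' \[-4, 4\]) and the reduced sets `Grid7` / `Grid5` (7 / 5 points on
#' \[-2.4, 2.4\]) motivated by the weight diagnostics; see
#' [weight_diagnostics()].
#'
#' @param per_dim Number of points per latent dimension (>= 1).
#' @param interval Length-2 numeric, `c(lo, hi)` with `lo < hi`.
#' @param K Number of latent dimensions.
#' @return An object of class `m2pl_grid` with fields `points` (G x K
#'   matrix), `per_dim`, `interval`, `K` and `G = per_dim^K`.
#' @export
build_grid <- function(per_dim, interval, K) {
  per_dim <- as.integer(per_dim)
  if (per_dim < 1L) stop("per_dim must be at least 1")
  if (length(interval) != 2 || interval[1] >= interval[2])
    stop("interval must be c(lo, hi) with lo < hi")
  K <- as.integer(K)
  if (K < 1L) stop("K must be positive")
  s <- if (per_dim == 1L) mean(interval) else
    seq(interval[1], interval[2], length.out = per_dim)
  ## last dimension fastest: column k repeats each value per_dim^(K-k) times
  pts <- matrix(0, per_dim^K, K)
  for (k in seq_len(K)) {
    pts[, k] <- rep(s, each = per_dim^(K - k), length.out = per_dim^K)
  }
  structure(
    list(points = pts, per_dim = per_dim,
         interval = as.numeric(interval), K = K, G = nrow(pts)),
    class = "m2pl_grid")
}

#' Convenience constructors for the standard grids
#'
#' `grid11(K)` gives 11 points per dimension on \[-4, 4\] (the reference
#' grid); `grid7(K)` and `grid5(K)` give 7 and 5 points per dimension on
#' \[-2.4, 2.4\] (the reduced grids; `grid5` is the recommended fast default
#' for K <= 5).  `grid3(K)` exists but is warned against: three points per
#' dimension are too coarse for the E-step expectation.
#'
#' @param K Number of latent dimensions.
#' @return An `m2pl_grid`.
#' @export
grid11 <- function(K) build_grid(11L, c(-4, 4), K)

#' @rdname grid11
#' @export
grid7 <- function(K) build_grid(7L, c(-2.4, 2.4), K)

#' @rdname grid11
#' @export
grid5 <- function(K) build_grid(5L, c(-2.4, 2.4), K)

#' @rdname grid11
#' @export
grid3 <- function(K) {
  warning("a 3-point-per-dimension grid is too coarse for reliable E-steps")
  build_grid(3L, c(-2.4, 2.4), K)
}

#' @export
print.m2pl_grid <- function(x, ...) {
  cat(sprintf("quadrature grid: %d^%d = %d points on [%g, %g]^%d\n",
              x$per_dim, x$K, x$G, x$interval[1], x$interval[2], x$K))
  invisible(x)
}

#' Group a response matrix into distinct patterns
#'
#' @param Y N x J binary response matrix.
#' @return List with `patterns` (P x J matrix of distinct rows), `counts`
#'   (multiplicities, summing to N) and `index` (length-N inverse map such
#'   that `patterns[index, ] == Y`).
#' @export
group_patterns <- function(Y) {
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  key <- do.call(paste, c(as.data.frame(Y), sep = ""))
  first <- !duplicated(key)
  patterns <- Y[first, , drop = FALSE]
  rownames(patterns) <- NULL
  index <- match(key, key[first])
  counts <- tabulate(index, nbins = nrow(patterns))
  list(patterns = patterns, counts = counts, index = index)
}

#' Discrete posterior of the latent traits over a grid
#'
#' Row i, column g holds the normalized posterior mass of grid point g for
#' response row i under the current parameters (prior density phi(theta_g |
#' Sigma) times the Bernoulli likelihood of the row, renormalized over g).
#' All per-row products are accumulated in log space and exponentiated after
#' subtracting the row maximum, so rows never underflow to all-zero.
#'
#' @param Y N x J binary response matrix.
#' @param A,b,Sigma Current item parameters and latent covariance.
#' @param grid An `m2pl_grid`.
#' @param group If `TRUE`, rows of the table correspond to distinct response
#'   patterns with multiplicities; downstream expected counts are identical
#'   either way.
#' @return An object of class `m2pl_posterior` with fields `weights` (P x G,
#'   rows summing to 1), `prior_density` (phi at the grid points), `counts`,
#'   `index`, `patterns`, `grouped` and `N`.
#' @export
posterior_table <- function(Y, A, b, Sigma, grid, group = FALSE) {
  check_item_params(A, b)
  check_latent_cov(Sigma)
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  if (ncol(Y) != nrow(A)) stop("Y and A disagree on the number of items")
  gp <- if (group) group_patterns(Y) else
    list(patterns = Y, counts = rep(1L, nrow(Y)), index = seq_len(nrow(Y)))
  L <- item_loglik_matrix(gp$patterns, A, b, grid)         # P x G
  logphi <- log_dmvnorm(grid$points, Sigma)
  M <- L + rep(logphi, each = nrow(L))
  rowmax <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  W <- exp(M - rowmax)
  W <- W / rowSums(W)
  structure(
    list(weights = W, prior_density = exp(logphi),
         counts = gp$counts, index = gp$index, patterns = gp$patterns,
         grouped = group, N = nrow(Y)),
    class = "m2pl_posterior")
}
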